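#' @include accessors.R
NULL

.aa3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
          "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL",
          "HID","HIE","HIP","CYX","CYM","ASH","GLH","LYN","MSE")

## Infer the element symbol from a PDB atom name when the element column is
## absent. Digits are stripped; names beginning with H (or nH for the
## 1HB-style hydrogens) are hydrogen; otherwise the leading character wins.
.infer_element <- function(name) {
  vapply(name, function(nm) {
    s <- gsub("[0-9' ]", "", nm)
    if (!nzchar(s)) return(NA_character_)
    if (substr(s, 1, 1) == "H") return("H")
    substr(s, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

.lookup_vdw <- function(element, radii = .vdw_table) {
  r <- unname(radii[element])
  r
}

#' Construct a StructureModel from an atom table and coordinates
#'
#' @param atoms data.frame with serial, name, element, resname, resid, chain.
#' @param coords n x 3 numeric matrix (Angstrom).
#' @param title description string.
#' @param radii named vector of van der Waals radii per element (Angstrom);
#'   defaults to the built-in table (C 1.70, N 1.55, O 1.52, S 1.80,
#'   P 1.80, H 1.20). Elements absent from the table get NA and only fail
#'   when an operation actually needs a radius.
#' @return a \linkS4class{StructureModel}
#' @export
StructureModel <- function(atoms, coords, title = "", radii = .vdw_table) {
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  storage.mode(coords) <- "double"
  atoms$vdw <- .lookup_vdw(atoms$element, radii)
  rownames(atoms) <- NULL
  new("StructureModel", atoms = atoms, coords = coords, title = title)
}

#' Construct a CoordinateEnsemble
#'
#' @param topology StructureModel shared by all frames.
#' @param frames list of n x 3 coordinate matrices.
#' @param frameInterval time per stored frame (informational).
#' @return a \linkS4class{CoordinateEnsemble}
#' @export
CoordinateEnsemble <- function(topology, frames, frameInterval = 1) {
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f); dimnames(f) <- NULL; storage.mode(f) <- "double"; f
  })
  new("CoordinateEnsemble", topology = topology, frames = frames,
      frameInterval = frameInterval)
}

.bio3d_to_atoms <- function(atom) {
  element <- atom$elesy
  miss <- is.na(element) | !nzchar(trimws(element))
  if (any(miss)) element[miss] <- .infer_element(atom$elety[miss])
  data.frame(
    serial = as.integer(atom$eleno),
    name = trimws(atom$elety),
    element = trimws(element),
    resname = trimws(atom$resid),
    resid = as.integer(atom$resno),
    chain = ifelse(is.na(atom$chain), " ", atom$chain),
    stringsAsFactors = FALSE)
}

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records (fixed columns, via bio3d); MODEL/ENDMDL
#' blocks select conformers. Elements are taken from columns 77-78 when
#' present and inferred from the atom name otherwise.
#'
#' @param path PDB file path.
#' @param modelIndex 1-based MODEL block to return; files without MODEL
#'   records are treated as a single model.
#' @param radii optional element radius table override.
#' @return a \linkS4class{StructureModel}
#' @export
readStructure <- function(path, modelIndex = 1L, radii = .vdw_table) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (modelIndex < 1L) stop("modelIndex must be >= 1")
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  nmod <- nrow(pdb$xyz)
  if (modelIndex > nmod)
    stop(sprintf("modelIndex %d beyond available models (%d)", modelIndex, nmod))
  xyz <- matrix(pdb$xyz[modelIndex, ], ncol = 3, byrow = TRUE)
  if (any(!is.finite(xyz))) stop("unparseable coordinates in ", path)
  StructureModel(.bio3d_to_atoms(pdb$atom), xyz,
                 title = basename(path), radii = radii)
}

#' Write a structure as a PDB file
#'
#' @param model StructureModel to write.
#' @param path output path.
#' @export
writeStructure <- function(model, path) {
  a <- model@atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(model@coords)),
                   resno = a$resid, resid = a$resname, eleno = a$serial,
                   elety = a$name, chain = ifelse(a$chain == " ", NA, a$chain),
                   elesy = a$element)
  invisible(path)
}

#' Select the C-alpha trace of a structure
#'
#' Retains atoms named CA within amino-acid residues, preserving order,
#' with one atom per residue (the first record wins on altloc duplicates).
#'
#' @param model StructureModel.
#' @return CA-only \linkS4class{StructureModel}
#' @export
selectCA <- function(model) {
  a <- model@atoms
  keep <- which(a$name == "CA" & a$resname %in% .aa3)
  if (length(keep) == 0) stop("no CA atoms found")
  key <- paste(a$chain[keep], a$resid[keep])
  keep <- keep[!duplicated(key)]
  out <- model
  out@atoms <- a[keep, , drop = FALSE]
  rownames(out@atoms) <- NULL
  out@coords <- model@coords[keep, , drop = FALSE]
  validObject(out)
  out
}

#' Stride-subsample the residues of a CA trace
#'
#' Keeps residues at ordinal positions 1, 1+stride, 1+2*stride, ...
#' (anchored at the first residue), so a chain of N residues yields
#' floor((N-1)/stride) + 1. Subsampling every 10 residues is the standard
#' preprocessing for residue-network methods capped around 150 nodes.
#'
#' @param model CA-only StructureModel.
#' @param stride positive integer step.
#' @return subsampled \linkS4class{StructureModel}
#' @export
subsampleResidues <- function(model, stride) {
  if (length(stride) != 1 || is.na(stride) || stride < 1 || stride != round(stride))
    stop("stride must be a positive integer")
  n <- nrow(model@coords)
  idx <- seq(1L, n, by = as.integer(stride))
  out <- model
  out@atoms <- model@atoms[idx, , drop = FALSE]
  rownames(out@atoms) <- NULL
  out@coords <- model@coords[idx, , drop = FALSE]
  out
}

.read_xyz_frames <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  frames <- list(); names_first <- NULL; i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1) stop("bad atom count line in XYZ file at line ", i)
    if (i + 1L + n > length(lines)) stop("truncated XYZ frame at line ", i)
    block <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(block), "\\s+")
    bad <- vapply(toks, function(t) length(t) < 4, logical(1))
    if (any(bad)) stop("unparseable XYZ atom line in frame starting line ", i)
    nm <- vapply(toks, `[`, character(1), 1)
    xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    if (any(!is.finite(xyz))) stop("non-numeric coordinate in XYZ frame at line ", i)
    if (is.null(names_first)) names_first <- nm
    else if (length(nm) != length(names_first))
      stop(sprintf("inconsistent atom counts across XYZ frames (%d vs %d)",
                   length(nm), length(names_first)))
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  if (length(frames) == 0) stop("no frames in XYZ file")
  list(names = names_first, frames = frames)
}

#' Read a coordinate ensemble
#'
#' Accepts a multi-model PDB (topology from the first model) or a plain
#' XYZ frame file (count line, comment line, then element x y z records,
#' repeated; atom count must be constant across frames).
#'
#' @param path input file.
#' @param format "auto" (by extension), "pdb" or "xyz".
#' @param frameInterval informational time per frame.
#' @return a \linkS4class{CoordinateEnsemble}
#' @export
readEnsemble <- function(path, format = c("auto", "pdb", "xyz"),
                         frameInterval = 1) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    topo <- StructureModel(.bio3d_to_atoms(pdb$atom),
                           matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE),
                           title = basename(path))
    fr <- lapply(seq_len(nrow(pdb$xyz)), function(f)
      matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE))
  } else {
    parsed <- .read_xyz_frames(path)
    n <- length(parsed$names)
    atoms <- data.frame(
      serial = seq_len(n), name = parsed$names,
      element = .infer_element(parsed$names),
      resname = rep("ALA", n), resid = seq_len(n),
      chain = rep("A", n), stringsAsFactors = FALSE)
    topo <- StructureModel(atoms, parsed$frames[[1]], title = basename(path))
    fr <- parsed$frames
  }
  CoordinateEnsemble(topo, fr, frameInterval = frameInterval)
}

#' Write a coordinate ensemble as a multi-model PDB
#'
#' @param ensemble CoordinateEnsemble.
#' @param path output file.
#' @export
writeEnsemble <- function(ensemble, path) {
  a <- ensemble@topology@atoms
  xyz <- do.call(rbind, lapply(ensemble@frames, function(f) as.vector(t(f))))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = a$resid, resid = a$resname, eleno = a$serial,
                   elety = a$name, chain = ifelse(a$chain == " ", NA, a$chain),
                   elesy = a$element)
  invisible(path)
}

#' Parse a residue selection string
#'
#' Accepts comma-separated indices and inclusive ranges, e.g.
#' \code{"804,907-914"}.
#'
#' @param sel selection string (or an already-numeric vector, returned
#'   as integers unchanged).
#' @return sorted unique integer vector
#' @export
parseResidueSelection <- function(sel) {
  if (is.numeric(sel)) return(sort(unique(as.integer(sel))))
  parts <- strsplit(gsub("\\s", "", sel), ",")[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0) stop("empty residue selection")
  out <- unlist(lapply(parts, function(p) {
    if (grepl("^-?[0-9]+--?[0-9]+$", p) || grepl("-", p)) {
      ab <- as.integer(strsplit(p, "-")[[1]])
      if (length(ab) != 2 || any(is.na(ab))) stop("bad selection token: ", p)
      seq(ab[1], ab[2])
    } else {
      v <- suppressWarnings(as.integer(p))
      if (is.na(v)) stop("bad selection token: ", p)
      v
    }
  }))
  sort(unique(out))
}
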