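#' @include methods.R
NULL

## PDB residue-name vocabulary for nucleotides; both DNA/RNA and legacy names
.purine_res <- c("DA", "DG", "A", "G", "ADE", "GUA", "RA", "RG")
.pyrimidine_res <- c("DC", "DT", "DU", "C", "T", "U", "CYT", "THY", "URA")
.nucleotide_res <- c(.purine_res, .pyrimidine_res)

## Sugar-phosphate heavy-atom names (primed convention; asterisked variants
## are normalized to primes on read).
.backbone_heavy <- c("P", "OP1", "OP2", "OP3", "O1P", "O2P", "O3P",
                     "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'",
                     "O2'", "C1'")
## Hydrogens that ride on the backbone/sugar.
.backbone_h_re <- "^(H|\\d*H)[0-9]*'+$|^HO[0-9]'$|^H5T$|^H3T$|^HOP[0-9]$"

.norm_name <- function(x) gsub("\\*", "'", x)

#' Read a molecular structure from PDB or XYZ
#'
#' PDB files are parsed with `bio3d` (ATOM and HETATM records; coordinates
#' keep PDB's three decimals).  XYZ files are the plain chemical format:
#' atom count, comment line, then `element x y z` rows; atoms are assigned
#' residue `MOL 1` on chain `A` and numbered names (`C1`, `C2`, ...) to keep
#' the (chain, residue, name) triple unique.  Asterisked sugar names
#' (`O5*`) are normalized to primed ones (`O5'`).
#'
#' @param path input file.
#' @param format `"pdb"`, `"xyz"`, or `"auto"` (by extension).
#' @return a [MolecularStructure-class].
#' @export
readStructure <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("pdb", "ent")) "pdb" else if (ext == "xyz")
      "xyz" else stop("cannot infer structure format from extension: ", path)
  }
  if (format == "pdb") .read_pdb(path) else .read_xyz(path)
}

.read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grep("^(ATOM  |HETATM)", lines)
  for (i in rec) {
    ln <- lines[i]
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      stop("malformed PDB coordinate record at line ", i, " of ", path)
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  at <- pdb$atom
  elem <- trimws(at$elesy)
  no_elem <- is.na(elem) | elem == ""
  if (any(no_elem))  # fall back to the leading letter(s) of the atom name
    elem[no_elem] <- sub("^[0-9]*([A-Za-z]).*$", "\\1",
                         trimws(at$elety[no_elem]))
  chain <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  MolecularStructure(
    data.frame(element = elem, name = .norm_name(trimws(at$elety)),
               resname = trimws(at$resid), resid = at$resno, chain = chain,
               x = at$x, y = at$y, z = at$z),
    metadata = list(source = path, format = "pdb"))
}

.read_xyz <- function(path) {
  lines <- .read_text_lines(path)
  if (length(lines) < 2) stop("malformed XYZ file (fewer than 2 lines): ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ atom count at line 1 of ", path)
  if (length(lines) < n + 2)
    stop("XYZ file declares ", n, " atoms but has only ",
         max(0, length(lines) - 2), " atom lines: ", path)
  el <- character(n); xyz <- matrix(NA_real_, n, 3)
  for (k in seq_len(n)) {
    fields <- strsplit(trimws(lines[k + 2]), "\\s+")[[1]]
    if (length(fields) < 4)
      stop("malformed XYZ atom record at line ", k + 2, " of ", path)
    el[k] <- fields[1]
    xyz[k, ] <- suppressWarnings(as.numeric(fields[2:4]))
    if (any(is.na(xyz[k, ])))
      stop("malformed XYZ coordinates at line ", k + 2, " of ", path)
  }
  counts <- stats::ave(seq_len(n), el, FUN = seq_along)
  MolecularStructure(
    data.frame(element = el, name = paste0(el, counts), resname = "MOL",
               resid = 1L, chain = "A",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
    metadata = list(source = path, format = "xyz",
                    comment = if (length(lines) >= 2) lines[2] else ""))
}

#' Write a structure in XYZ format
#'
#' Emits the atom count, one comment line, then `element x y z` with six
#' decimals.
#'
#' @param structure a [MolecularStructure-class].
#' @param path output path.
#' @param comment comment line content.
#' @return `path`, invisibly.
#' @export
writeXyz <- function(structure, path, comment = "written by ecdtools") {
  stopifnot(is(structure, "MolecularStructure"))
  at <- structure@atoms
  writeLines(c(sprintf("%d", nrow(at)), comment,
               sprintf("%-2s %12.6f %12.6f %12.6f", at$element,
                       at$x, at$y, at$z)), path)
  invisible(path)
}

#' Excise the sugar-phosphate backbone from nucleotide residues
#'
#' Removes the standard backbone and sugar atoms (P, OP1/OP2 and variants,
#' O5', C5', C4', O4', C3', O3', C2', O2', C1', plus their hydrogens) from
#' every residue whose name identifies a nucleotide; all other species
#' (metal ions, waters, anything non-nucleotide) pass through untouched.
#' For each nucleotide that loses its C1', one cut bond is recorded at the
#' glycosidic linkage: C1'-N9 for purines, C1'-N1 for pyrimidines.  The
#' operation is idempotent: a structure without backbone atoms is returned
#' unchanged with zero cut bonds.
#'
#' @param structure a [MolecularStructure-class].
#' @return list with `structure` (the base-only [MolecularStructure-class])
#'   and `cutBonds`: a data.frame with one row per severed glycosidic bond
#'   (`chain`, `resid`, `resname`, `base_atom`, base-nitrogen coordinates
#'   `nx,ny,nz`, removed-C1' coordinates `cx,cy,cz`).
#' @seealso [capWithHydrogens()]
#' @export
stripBackbone <- function(structure) {
  stopifnot(is(structure, "MolecularStructure"))
  at <- structure@atoms
  is_nt <- toupper(at$resname) %in% .nucleotide_res
  name <- .norm_name(at$name)
  is_bb <- is_nt & (name %in% .backbone_heavy | grepl(.backbone_h_re, name))
  cut <- list()
  for (key in unique(paste(at$chain, at$resid)[is_nt])) {
    sel <- paste(at$chain, at$resid) == key & is_nt
    res <- at[sel, , drop = FALSE]
    rname <- toupper(res$resname[1])
    c1 <- res[.norm_name(res$name) == "C1'", , drop = FALSE]
    if (nrow(c1) == 0) next  # already truncated
    gly <- if (rname %in% .purine_res) "N9" else "N1"
    nat <- res[res$name == gly, , drop = FALSE]
    if (nrow(nat) == 0)
      stop("residue ", res$resname[1], " ", res$resid[1], " (chain ",
           res$chain[1], ") lacks the expected glycosidic nitrogen ", gly)
    cut[[length(cut) + 1]] <- data.frame(
      chain = nat$chain, resid = nat$resid, resname = res$resname[1],
      base_atom = gly, nx = nat$x, ny = nat$y, nz = nat$z,
      cx = c1$x, cy = c1$y, cz = c1$z)
  }
  cutBonds <- if (length(cut)) do.call(rbind, cut) else
    data.frame(chain = character(), resid = integer(), resname = character(),
               base_atom = character(), nx = numeric(), ny = numeric(),
               nz = numeric(), cx = numeric(), cy = numeric(), cz = numeric())
  rownames(cutBonds) <- NULL
  list(structure = MolecularStructure(at[!is_bb, , drop = FALSE],
                                      metadata = structure@metadata),
       cutBonds = cutBonds)
}

#' Cap severed glycosidic bonds with hydrogens
#'
#' Places one hydrogen per cut bond along the unit vector from the
#' glycosidic nitrogen toward the removed C1' position, at a fixed N-H
#' distance (default 1.01 Angstrom, the standard amine N-H length; this is
#' the pre-relaxation geometric guess -- any subsequent quantum-mechanical
#' relaxation of the caps is outside this package's scope).  Added atoms
#' are named H9 (purines) or H1 (pyrimidines).  Pre-existing atoms are
#' never moved.
#'
#' @param baseOnly the truncated [MolecularStructure-class] from
#'   [stripBackbone()].
#' @param cutBonds the `cutBonds` data.frame from [stripBackbone()].
#' @param nhLength N-H bond length in Angstrom (default 1.01).
#' @return a [MolecularStructure-class] with `nrow(cutBonds)` added H atoms.
#' @export
capWithHydrogens <- function(baseOnly, cutBonds, nhLength = 1.01) {
  stopifnot(is(baseOnly, "MolecularStructure"))
  at <- baseOnly@atoms
  if (nrow(cutBonds) == 0) return(baseOnly)
  caps <- list()
  for (k in seq_len(nrow(cutBonds))) {
    b <- cutBonds[k, ]
    sel <- at$chain == b$chain & at$resid == b$resid & at$name == b$base_atom
    if (!any(sel))
      stop("cut-bond base atom ", b$base_atom, " missing in residue ",
           b$resname, " ", b$resid)
    v <- c(b$cx - b$nx, b$cy - b$ny, b$cz - b$nz)
    len <- sqrt(sum(v^2))
    if (len == 0)
      stop("geometry error: zero-length glycosidic bond vector in residue ",
           b$resname, " ", b$resid)
    h <- c(b$nx, b$ny, b$nz) + nhLength * v / len
    caps[[k]] <- data.frame(
      element = "H", name = if (b$base_atom == "N9") "H9" else "H1",
      resname = b$resname, resid = b$resid, chain = b$chain,
      x = h[1], y = h[2], z = h[3])
  }
  MolecularStructure(rbind(at, do.call(rbind, caps)),
                     metadata = baseOnly@metadata)
}
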