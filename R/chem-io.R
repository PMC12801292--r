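#' @include AllClasses.R
NULL

#' Construct a Molecule
#'
#' @param id compound identifier (single string).
#' @param elements character vector of element symbols.
#' @param coords numeric n x 3 matrix of coordinates in Angstrom, or `NULL`
#'   for a topology-only molecule.
#' @param bonds m x 3 matrix `(atom1, atom2, order)`, or `NULL` for none.
#' @param charges integer formal charges (default all zero).
#' @param meta list of record metadata (e.g. `smiles`, SDF data fields).
#' @return a [Molecule-class].
#' @examples
#' ethane <- Molecule("ethane", c("C", "C"),
#'                    coords = rbind(c(0, 0, 0), c(1.54, 0, 0)),
#'                    bonds = cbind(1, 2, 1))
#' @export
Molecule <- function(id, elements, coords = NULL, bonds = NULL,
                     charges = NULL, meta = list()) {
  n <- length(elements)
  if (is.null(coords)) coords <- matrix(NA_real_, n, 3)
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (is.null(bonds)) bonds <- matrix(integer(), 0, 3)
  bonds <- matrix(as.integer(bonds), ncol = 3)
  if (is.null(charges)) charges <- rep(0L, n)
  new("Molecule", id = as.character(id), elements = as.character(elements),
      coords = coords, bonds = bonds, charges = as.integer(charges),
      meta = meta)
}

#' Construct a PoseRecord
#'
#' @param compoundId,structureId identifiers (whitespace-trimmed, compared
#'   case-sensitively).
#' @param conformer a [Molecule-class] with coordinates.
#' @param dockingScore engine score; more negative = better.
#' @return a [PoseRecord-class].
#' @export
PoseRecord <- function(compoundId, structureId, conformer, dockingScore) {
  new("PoseRecord", compoundId = trimws(compoundId),
      structureId = trimws(structureId), conformer = conformer,
      dockingScore = as.numeric(dockingScore))
}

# ---- SDF ----

# Record-level validity: a parsed atom block with coordinates and, when
# bonds are present, a parsed bond block. (ChemmineR::validSDF() would
# reject legitimate bond-less records such as single heavy atoms.)
.sdf_record_ok <- function(sdf) {
  ab <- try(ChemmineR::atomblock(sdf), silent = TRUE)
  if (inherits(ab, "try-error") || !is.matrix(ab) || nrow(ab) < 1 ||
      ncol(ab) < 3 || anyNA(ab))
    return(FALSE)
  bb <- try(ChemmineR::bondblock(sdf), silent = TRUE)
  if (inherits(bb, "try-error")) return(FALSE)
  if (is.matrix(bb) && nrow(bb) > 0 && (ncol(bb) < 3 || anyNA(bb)))
    return(FALSE)
  TRUE
}

.sdf_to_molecule <- function(sdf, id = NULL) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_\\d+$", "", rownames(ab))
  coords <- unname(ab[, 1:3, drop = FALSE])
  bonds <- if (length(bb) && nrow(bb)) unname(bb[, 1:3, drop = FALSE])
           else NULL
  db <- ChemmineR::datablock(sdf)
  meta <- if (length(db)) as.list(db) else list()
  name <- ChemmineR::header(sdf)[["Molecule_Name"]]
  Molecule(id %||% (if (nzchar(trimws(name))) trimws(name) else "unnamed"),
           elements, coords, bonds, meta = meta)
}

#' Read molecules from an SDF (V2000) file
#'
#' Parses each record into a [Molecule-class], preserving coordinates and
#' record-level data fields. Corrupt records are dropped with a warning, not
#' an error; their count is available as `attr(result, "nFailed")`.
#'
#' @param path SDF file path.
#' @return list of [Molecule-class] objects.
#' @export
readMoleculesSDF <- function(path) {
  .assert(file.exists(path), "cannot read SDF: no such file: ", path)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(path, skipErrors = TRUE))
  ok <- vapply(seq_along(sdfs), function(i) .sdf_record_ok(sdfs[[i]]),
               logical(1))
  nfail <- sum(!ok)
  sdfs <- sdfs[ok]
  .assert(length(sdfs) > 0, "no valid SDF records in ", path)
  if (nfail > 0)
    warning(nfail, " corrupt SDF record(s) dropped from ", path)
  mols <- lapply(seq_along(sdfs), function(i) .sdf_to_molecule(sdfs[[i]]))
  # fall back to record position for unnamed records
  for (i in seq_along(mols))
    if (mols[[i]]@id == "unnamed") mols[[i]]@id <- paste0("mol_", i)
  attr(mols, "nFailed") <- nfail
  mols
}

.molecule_to_sdf_text <- function(mol) {
  n <- length(mol@elements)
  nb <- nrow(mol@bonds)
  xyz <- mol@coords
  xyz[is.na(xyz)] <- 0
  lines <- c(
    mol@id, "  PharmScreen", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            xyz[, 1], xyz[, 2], xyz[, 3], mol@elements))
  if (nb > 0)
    lines <- c(lines, sprintf("%3d%3d%3d  0", mol@bonds[, 1], mol@bonds[, 2],
                              mol@bonds[, 3]))
  chg <- which(mol@charges != 0L)
  if (length(chg))
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg)),
                             paste0(sprintf("%4d%4d", chg, mol@charges[chg]),
                                    collapse = "")))
  lines <- c(lines, "M  END")
  meta <- mol@meta
  meta <- meta[vapply(meta, function(v) is.atomic(v) && length(v) == 1,
                      logical(1))]
  for (tag in names(meta))
    lines <- c(lines, paste0(">  <", tag, ">"), as.character(meta[[tag]]), "")
  c(lines, "$$$$")
}

#' Write molecules to an SDF (V2000) file
#'
#' Heavy-atom graphs and coordinates survive a write/read round trip to
#' better than 1e-3 Angstrom (coordinates are written at 1e-4 precision).
#' Scalar metadata entries are written as SDF data fields.
#'
#' @param mols a [Molecule-class] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMoleculesSDF <- function(mols, path) {
  if (is(mols, "Molecule")) mols <- list(mols)
  txt <- unlist(lapply(mols, .molecule_to_sdf_text))
  writeLines(txt, path)
  invisible(path)
}

# ---- SMILES ----

#' Read a SMILES file
#'
#' One molecule per line: `SMILES[<whitespace>id]`. Missing ids become
#' `mol_<line>`.
#'
#' @param path SMILES file path.
#' @return named character vector of SMILES (names = ids).
#' @export
readSmilesFile <- function(path) {
  .assert(file.exists(path), "no such file: ", path)
  ln <- trimws(readLines(path))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  .assert(length(ln) > 0, "no SMILES records in ", path)
  parts <- strsplit(ln, "[ \t]+")
  smi <- vapply(parts, `[`, character(1), 1L)
  ids <- vapply(seq_along(parts), function(i)
    if (length(parts[[i]]) > 1) parts[[i]][2] else paste0("mol_", i),
    character(1))
  stats::setNames(smi, ids)
}

#' Convert SMILES to a ChemmineR SDFset
#'
#' Thin wrapper over [ChemmineR::smiles2sdf()] (OpenBabel-backed) that keeps
#' compound ids on the set and tolerates per-record failures.
#'
#' @param smiles named character vector of SMILES.
#' @return an `SDFset` with `cid` set to the input names; unparseable
#'   entries are dropped and recorded in `attr(, "failed")`.
#' @export
smilesToSDFset <- function(smiles) {
  ids <- names(smiles) %||% paste0("mol_", seq_along(smiles))
  keep <- logical(length(smiles))
  sdfs <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    s <- try(suppressWarnings(ChemmineR::smiles2sdf(
      stats::setNames(smiles[[i]], ids[i]))), silent = TRUE)
    if (!inherits(s, "try-error") && length(s) == 1 &&
        .sdf_record_ok(s[[1]])) {
      sdfs[[i]] <- s[[1]]
      keep[i] <- TRUE
    }
  }
  .assert(any(keep), "no SMILES could be parsed")
  set <- new("SDFset", SDF = sdfs[keep], ID = ids[keep])
  attr(set, "failed") <- ids[!keep]
  set
}

# ---- PDB receptors ----

.elem_from_pdb <- function(elesy, elety) {
  e <- trimws(elesy)
  miss <- !nzchar(e) | is.na(e)
  if (any(miss)) {
    # derive from the atom name: strip digits, take leading one/two letters
    nm <- gsub("[0-9']", "", trimws(elety[miss]))
    e[miss] <- ifelse(substr(nm, 1, 2) %in% c("CL", "BR"),
                      substr(nm, 1, 2), substr(nm, 1, 1))
  }
  paste0(toupper(substr(e, 1, 1)), tolower(substr(e, 2, 2)))
}

#' Read a receptor structure from a PDB file
#'
#' Waters (HOH/WAT/DOD) and heteroatom records are excluded unless
#' explicitly retained; residue numbering is taken verbatim from the file.
#' Only alternate location 'A' or blank is kept, giving one deterministic
#' conformation.
#'
#' @param path PDB file path.
#' @param chains optional chain filter (character vector), e.g. `"A"`.
#' @param keepHet keep non-water HETATM records (default `FALSE`).
#' @param bindingSite optional data.frame (chain, resno) restricting the
#'   interaction-detection site.
#' @param id structure identifier; defaults to the file base name.
#' @return a [ReceptorStructure-class].
#' @export
readPDBReceptor <- function(path, chains = NULL, keepHet = FALSE,
                            bindingSite = NULL, id = NULL) {
  .assert(file.exists(path), "no such file: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  water <- at$resid %in% c("HOH", "WAT", "DOD")
  keep <- (at$type == "ATOM" | (keepHet & at$type == "HETATM")) & !water
  keep <- keep & (is.na(at$alt) | at$alt %in% c("", "A"))
  if (!is.null(chains)) keep <- keep & at$chain %in% chains
  at <- at[keep, , drop = FALSE]
  .assert(nrow(at) > 0, "no protein atoms in ", path)
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = as.integer(at$resno),
    resname = trimws(at$resid),
    atom = trimws(at$elety),
    elem = .elem_from_pdb(at$elesy, at$elety),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE)
  if (is.null(bindingSite))
    bindingSite <- data.frame(chain = character(), resno = integer())
  new("ReceptorStructure",
      id = id %||% sub("\\.pdb$", "", basename(path), ignore.case = TRUE),
      atoms = atoms, bindingSite = bindingSite)
}

#' Write a receptor structure as a PDB file
#'
#' Fixed-format ATOM records; output is byte-deterministic for a given
#' structure.
#'
#' @param x a [ReceptorStructure-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReceptorPDB <- function(x, path) {
  at <- x@atoms
  name4 <- ifelse(nchar(at$atom) < 4, paste0(" ", at$atom), at$atom)
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(at)), name4, at$resname, at$chain, at$resno,
    at$x, at$y, at$z, 1, 0, toupper(at$elem))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# ---- pose sets and score manifests ----

#' Read a docking-score manifest
#'
#' CSV with header `compound_id,structure_id,docking_score,pose_file`.
#' Identifiers are whitespace-trimmed and compared case-sensitively.
#'
#' @param path manifest CSV path.
#' @return data.frame with the four columns validated.
#' @export
readScoreManifest <- function(path) {
  .assert(file.exists(path), "no such file: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "structure_id", "docking_score", "pose_file")
  .assert(all(need %in% names(m)),
          "manifest must have columns: ", paste(need, collapse = ", "))
  m$compound_id <- trimws(m$compound_id)
  m$structure_id <- trimws(m$structure_id)
  .assert(all(is.finite(m$docking_score)), "non-finite docking scores")
  key <- paste(m$compound_id, m$structure_id, sep = "\r")
  dup <- duplicated(key)
  .assert(!any(dup), "duplicate (compound_id, structure_id) rows: ",
          paste(unique(sprintf("(%s, %s)", m$compound_id[dup],
                               m$structure_id[dup])), collapse = "; "))
  m
}

#' Load a pose set from a manifest and a pose directory
#'
#' One [PoseRecord-class] per manifest row. Pose files are SDF; the first
#' record of each file is used. All missing pose files are collected and
#' reported in a single error.
#'
#' @param manifestPath manifest CSV (see [readScoreManifest()]).
#' @param poseDir directory against which relative `pose_file` paths are
#'   resolved.
#' @return list of [PoseRecord-class] objects.
#' @export
loadPoseSet <- function(manifestPath, poseDir = dirname(manifestPath)) {
  m <- readScoreManifest(manifestPath)
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", m$pose_file), m$pose_file,
                  file.path(poseDir, m$pose_file))
  missing <- !file.exists(paths)
  .assert(!any(missing), "missing pose file(s):\n  ",
          paste(unique(paths[missing]), collapse = "\n  "))
  lapply(seq_len(nrow(m)), function(i) {
    mol <- readMoleculesSDF(paths[i])[[1]]
    mol@id <- m$compound_id[i]
    PoseRecord(m$compound_id[i], m$structure_id[i], mol, m$docking_score[i])
  })
}

#' Write a pose set and its score manifest
#'
#' @param poses list of [PoseRecord-class] objects.
#' @param dir output directory (created if absent).
#' @param manifest manifest file name within `dir`.
#' @return the manifest path, invisibly.
#' @export
writePoseSet <- function(poses, dir, manifest = "manifest.csv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(poses, function(p) {
    fn <- paste0(p@compoundId, "_", p@structureId, ".sdf")
    writeMoleculesSDF(p@conformer, file.path(dir, fn))
    data.frame(compound_id = p@compoundId, structure_id = p@structureId,
               docking_score = p@dockingScore, pose_file = fn,
               stringsAsFactors = FALSE)
  })
  m <- do.call(rbind, rows)
  path <- file.path(dir, manifest)
  utils::write.csv(m, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
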