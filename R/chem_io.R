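#' Read molecular structures from SDF, MOL2 or XYZ files
#'
#' Parses pre-optimised 3D geometries into [molecule()] objects.  Supported
#' dialects: SDF (V2000 connection tables, `$$$$`-separated), Tripos MOL2
#' (`@<TRIPOS>ATOM` blocks) and plain XYZ (multi-record, or a bare atom list
#' without the count header).  Van der Waals radii are assigned from
#' `radius_table` since none of these formats carries them.
#'
#' @param path Path to the structure file.
#' @param format One of `"sdf"`, `"mol2"`, `"xyz"`; default is guessed from
#'   the file extension.
#' @param radius_table Element-to-radius lookup, default [vdw_radii_table()].
#' @return List of [molecule()] objects.
#' @export
read_structures <- function(path, format = NULL,
                            radius_table = vdw_radii_table()) {
  if (!file.exists(path)) stop("structure file does not exist: ", path)
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("sdf", "mol", "mol2", "xyz"))
      stop("cannot guess format from extension '", format,
           "'; pass format explicitly")
    if (format == "mol") format <- "sdf"
  }
  format <- match.arg(tolower(format), c("sdf", "mol2", "xyz"))
  lines <- readLines(path, warn = FALSE)
  switch(format,
         sdf = read_sdf_lines(lines, radius_table),
         mol2 = read_mol2_lines(lines, radius_table),
         xyz = read_xyz_lines(lines, radius_table))
}

normalize_element <- function(sym) {
  sym <- sub("\\..*$", "", sym)              # strip MOL2 subtype, e.g. C.ar
  sym <- gsub("[^A-Za-z]", "", sym)
  ifelse(nchar(sym) == 0L, sym,
         paste0(toupper(substr(sym, 1L, 1L)),
                tolower(substr(sym, 2L, nchar(sym)))))
}

read_sdf_lines <- function(lines, radius_table) {
  # split into records on the $$$$ delimiter
  delim <- grep("^\\${4}", lines)
  starts <- c(1L, delim + 1L)
  ends <- c(delim - 1L, length(lines))
  mols <- list()
  rec_no <- 0L
  for (k in seq_along(starts)) {
    if (starts[k] > length(lines) || starts[k] > ends[k]) next
    rec <- lines[seq.int(starts[k], min(ends[k], length(lines)))]
    # drop blank filler between $$$$ and the next header
    nonblank <- which(nzchar(trimws(rec)))
    if (length(nonblank) == 0L) next
    rec <- rec[nonblank[1L]:length(rec)]
    rec_no <- rec_no + 1L
    if (length(rec) < 4L)
      stop("SDF record ", rec_no, ": truncated header block")
    counts <- strsplit(trimws(rec[4L]), "\\s+")[[1]]
    natoms <- suppressWarnings(as.integer(counts[1L]))
    if (is.na(natoms) || natoms < 1L)
      stop("SDF record ", rec_no, ": unparseable counts line")
    if (length(rec) < 4L + natoms)
      stop("SDF record ", rec_no, ": atom block shorter than counts line")
    atom_lines <- rec[5:(4L + natoms)]
    parsed <- lapply(seq_along(atom_lines), function(i) {
      f <- strsplit(trimws(atom_lines[i]), "\\s+")[[1]]
      xyz <- suppressWarnings(as.numeric(f[1:3]))
      if (length(f) < 4L || anyNA(xyz))
        stop("SDF record ", rec_no, ": malformed atom line ", i)
      list(xyz = xyz, el = normalize_element(f[4L]))
    })
    id <- trimws(rec[1L])
    if (!nzchar(id)) id <- paste0("mol", rec_no)
    mols[[rec_no]] <- molecule(
      id = id,
      elements = vapply(parsed, `[[`, "", "el"),
      coords = do.call(rbind, lapply(parsed, `[[`, "xyz")),
      radius_table = radius_table)
  }
  if (rec_no == 0L) stop("no SDF records found")
  mols
}

read_mol2_lines <- function(lines, radius_table) {
  mol_starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (length(mol_starts) == 0L) stop("no @<TRIPOS>MOLECULE record found")
  mols <- vector("list", length(mol_starts))
  bounds <- c(mol_starts, length(lines) + 1L)
  for (k in seq_along(mol_starts)) {
    rec_idx <- seq.int(bounds[k], bounds[k + 1L] - 1L)
    rec <- lines[rec_idx]
    id <- trimws(rec[2L])
    if (is.na(id) || !nzchar(id)) id <- paste0("mol", k)
    astart <- grep("^@<TRIPOS>ATOM", rec)
    if (length(astart) == 0L)
      stop("MOL2 record ", k, ": missing @<TRIPOS>ATOM section")
    astart <- astart[1L] + 1L
    aend <- astart - 1L
    while (aend + 1L <= length(rec) &&
           !grepl("^@<TRIPOS>", rec[aend + 1L]) &&
           nzchar(trimws(rec[aend + 1L]))) aend <- aend + 1L
    if (aend < astart) stop("MOL2 record ", k, ": empty atom section")
    atoms <- lapply(seq.int(astart, aend), function(i) {
      f <- strsplit(trimws(rec[i]), "\\s+")[[1]]
      xyz <- suppressWarnings(as.numeric(f[3:5]))
      if (length(f) < 6L || anyNA(xyz))
        stop("MOL2 record ", k, ": malformed atom line ",
             rec_idx[i], " ('", trimws(rec[i]), "')")
      q <- if (length(f) >= 9L) suppressWarnings(as.numeric(f[9L])) else NA_real_
      list(xyz = xyz, el = normalize_element(f[6L]), q = q)
    })
    charges <- vapply(atoms, `[[`, 0, "q")
    mols[[k]] <- molecule(
      id = id,
      elements = vapply(atoms, `[[`, "", "el"),
      coords = do.call(rbind, lapply(atoms, `[[`, "xyz")),
      charges = if (anyNA(charges)) NULL else charges,
      radius_table = radius_table)
  }
  mols
}

read_xyz_lines <- function(lines, radius_table) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty XYZ file")
  first_count <- suppressWarnings(as.integer(trimws(lines[1L])))
  parse_atoms <- function(atom_lines, rec_no) {
    parsed <- lapply(seq_along(atom_lines), function(i) {
      f <- strsplit(trimws(atom_lines[i]), "\\s+")[[1]]
      xyz <- suppressWarnings(as.numeric(f[2:4]))
      if (length(f) < 4L || anyNA(xyz))
        stop("XYZ record ", rec_no, ": malformed atom line ", i)
      list(el = normalize_element(f[1L]), xyz = xyz)
    })
    list(elements = vapply(parsed, `[[`, "", "el"),
         coords = do.call(rbind, lapply(parsed, `[[`, "xyz")))
  }
  if (is.na(first_count)) {
    # headerless dialect: the whole file is one atom list
    at <- parse_atoms(lines, 1L)
    return(list(molecule("mol1", at$elements, at$coords,
                         radius_table = radius_table)))
  }
  mols <- list()
  i <- 1L
  rec_no <- 0L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    rec_no <- rec_no + 1L
    if (is.na(n) || n < 1L)
      stop("XYZ record ", rec_no, ": bad atom count line")
    if (i + 1L + n > length(lines))
      stop("XYZ record ", rec_no, ": truncated atom block")
    id <- trimws(lines[i + 1L])
    if (!nzchar(id)) id <- paste0("mol", rec_no)
    at <- parse_atoms(lines[(i + 2L):(i + 1L + n)], rec_no)
    mols[[rec_no]] <- molecule(id, at$elements, at$coords,
                               radius_table = radius_table)
    i <- i + 2L + n
  }
  mols
}

#' Transform IC50 to the modelling activity scale
#'
#' Applies the shifted negative-log transform `activity = 6 - log10(IC50)`
#' with IC50 in micromolar.  The shift places micromolar potencies on a
#' convenient positive scale (1 uM maps to 6, equivalently -log10 of the
#' molar concentration).
#'
#' @param ic50 Numeric vector of IC50 values in micromolar; must be > 0.
#' @return Numeric vector of transformed activities.
#' @examples
#' transform_activity(1)     # 6
#' transform_activity(15.41) # compound with IC50 15.41 uM
#' @export
transform_activity <- function(ic50) {
  ic50 <- as.numeric(ic50)
  if (any(!is.finite(ic50)) || any(ic50 <= 0))
    stop("IC50 values must be finite and > 0 (micromolar)")
  6 - log10(ic50)
}

#' Invert the activity transform
#' @param activity Transformed activity values.
#' @return IC50 in micromolar.
#' @export
inverse_transform_activity <- function(activity) {
  10^(6 - as.numeric(activity))
}

#' Read an activity table
#'
#' CSV with header `compound_id,ic50_uM` (extra columns are preserved).  Adds
#' the transformed `activity` column.
#'
#' @param path CSV path.
#' @return data.frame with at least `compound_id`, `ic50_uM`, `activity`.
#' @export
read_activity_csv <- function(path) {
  if (!file.exists(path)) stop("activity file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("compound_id", "ic50_uM")
  if (!all(req %in% names(df)))
    stop("activity CSV must have columns: ", paste(req, collapse = ", "))
  df$compound_id <- as.character(df$compound_id)
  df$activity <- transform_activity(df$ic50_uM)
  df
}

#' Write an activity table with its transformed column
#' @param df data.frame with `compound_id` and `ic50_uM`.
#' @param path Output CSV path.
#' @return Invisibly, the augmented data.frame.
#' @export
write_activity_csv <- function(df, path) {
  if (is.null(df$activity)) df$activity <- transform_activity(df$ic50_uM)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Random train/test split of activity records
#'
#' Uniform random partition of compound ids into a training and a test set,
#' reproducible under a fixed seed.  Mirrors the small-sample protocol of
#' splitting 50 compounds into 40 training and 10 test members.
#'
#' @param ids Character vector of compound ids (or a data.frame with a
#'   `compound_id` column).
#' @param n_train,n_test Requested set sizes; must sum to `length(ids)`.
#' @param seed Integer seed.
#' @return List with `train_ids`, `test_ids`, `seed` (class `dataset_split`).
#' @export
split_dataset <- function(ids, n_train, n_test, seed) {
  if (is.data.frame(ids)) ids <- ids$compound_id
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("compound ids must be unique")
  if (n_train + n_test != length(ids))
    stop("n_train + n_test (", n_train + n_test,
         ") must equal the number of records (", length(ids), ")")
  if (n_train < 1L || n_test < 0L) stop("set sizes must be positive")
  test_ids <- withr_seed(seed, sample(ids, n_test))
  structure(list(train_ids = setdiff(ids, test_ids),
                 test_ids = test_ids, seed = as.integer(seed)),
            class = "dataset_split")
}

# run expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
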