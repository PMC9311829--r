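#' Construct a landmark dataset
#'
#' The container for one bilateral structure: a k x 2 x n coordinate
#' array plus per-configuration classifier metadata. Under matching
#' symmetry (paired structures such as wings) each configuration belongs
#' to one side, `"left"` or `"right"`. Under object symmetry (a single
#' structure with an internal midline, such as a head) `side` is
#' `"none"` and a landmark `pairing` maps left landmarks to their right
#' counterparts, with the remainder on the midline.
#'
#' @param coords k x 2 x n array (or list of k x 2 matrices) of landmark
#'   coordinates, k >= 3.
#' @param info data frame with n rows; recognized columns:
#'   `specimen_id`, `individual`, `side` (`"left"`/`"right"`/`"none"`),
#'   `image_rep`, `digit_rep`, `nest`, `location`, `species`. Missing
#'   classifier columns are filled with defaults (`image_rep` and
#'   `digit_rep` default to 1; `side` defaults per `symmetry_mode`).
#' @param symmetry_mode `"matching"` or `"object"`.
#' @param pairing for object mode, a list with `pairs` (2-column matrix
#'   of 1-based landmark indices, left then right) and `midline`
#'   (integer vector); validated with [validate_pairing()].
#' @param meta optional list (length n) of named character vectors of
#'   opaque per-record metadata carried through I/O.
#' @return an object of class `landmark_dataset`.
#' @export
landmark_dataset <- function(coords, info = NULL,
                             symmetry_mode = c("matching", "object"),
                             pairing = NULL, meta = NULL) {
  symmetry_mode <- match.arg(symmetry_mode)
  A <- coords_array(coords)
  k <- dim(A)[1L]
  n <- dim(A)[3L]
  if (k < 3L) stop("a landmark dataset needs k >= 3 landmarks")
  if (is.null(info)) info <- data.frame(specimen_id = sprintf("spec%03d", seq_len(n)))
  info <- as.data.frame(info, stringsAsFactors = FALSE)
  if (nrow(info) != n) stop("info must have one row per configuration")
  if (is.null(info$specimen_id)) info$specimen_id <- sprintf("spec%03d", seq_len(n))
  if (is.null(info$individual)) info$individual <- info$specimen_id
  if (is.null(info$side)) {
    info$side <- if (symmetry_mode == "object") "none" else
      stop("matching symmetry requires a 'side' classifier (left/right)")
  }
  if (is.null(info$image_rep)) info$image_rep <- 1L
  if (is.null(info$digit_rep)) info$digit_rep <- 1L
  info$image_rep <- as.integer(info$image_rep)
  info$digit_rep <- as.integer(info$digit_rep)
  if (any(info$image_rep < 1L) || any(info$digit_rep < 1L))
    stop("image_rep and digit_rep must be >= 1")
  side_ok <- if (symmetry_mode == "matching") c("left", "right") else "none"
  bad <- setdiff(unique(info$side), side_ok)
  if (length(bad))
    stop("invalid side value(s) for ", symmetry_mode, " symmetry: ",
         paste(bad, collapse = ", "))
  if (symmetry_mode == "object") {
    if (is.null(pairing)) stop("object symmetry requires a landmark pairing")
    pairing <- validate_pairing(pairing$pairs, pairing$midline, k)
  } else {
    pairing <- NULL
  }
  if (!is.null(meta) && length(meta) != n)
    stop("meta must have one entry per configuration")
  structure(list(coords = A, info = info, k = k,
                 symmetry_mode = symmetry_mode, pairing = pairing,
                 meta = meta),
            class = "landmark_dataset")
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat(sprintf("Landmark dataset: %d configurations, k = %d, %s symmetry\n",
              dim(x$coords)[3L], x$k, x$symmetry_mode))
  cat(sprintf("  individuals: %d", length(unique(x$info$individual))))
  if (x$symmetry_mode == "matching")
    cat(sprintf("   sides: %s", paste(sort(unique(x$info$side)), collapse = "/")))
  cat("\n")
  invisible(x)
}

#' Number of configurations in a landmark dataset
#' @param x a `landmark_dataset`.
#' @return integer count.
#' @export
n_configs <- function(x) dim(x$coords)[3L]

#' Validate a landmark pairing for object symmetry
#'
#' Checks that the left/right pairs plus midline indices partition
#' `1..k` and that the pairing is a fixed-point-free involution on the
#' paired indices.
#'
#' @param pairs 2-column matrix (or list of length-2 vectors) of 1-based
#'   landmark indices; column 1 is the left member, column 2 the right.
#' @param midline integer vector of midline landmark indices (may be
#'   empty).
#' @param k total landmark count.
#' @return a list with `pairs` (integer matrix) and `midline` (sorted
#'   integer vector); errors list every duplicated or unassigned index.
#' @export
validate_pairing <- function(pairs, midline = integer(), k) {
  if (is.list(pairs) && !is.matrix(pairs))
    pairs <- do.call(rbind, lapply(pairs, as.integer))
  pairs <- matrix(as.integer(as.matrix(pairs)), ncol = 2L)
  midline <- sort(as.integer(midline))
  all_idx <- c(as.vector(pairs), midline)
  if (any(!is.finite(all_idx)) || any(all_idx < 1L) || any(all_idx > k))
    stop("pairing indices must lie in 1..", k)
  if (any(pairs[, 1L] == pairs[, 2L]))
    stop("a landmark cannot be paired with itself")
  dup <- unique(all_idx[duplicated(all_idx)])
  if (length(dup))
    stop("landmark index assigned more than once: ", paste(dup, collapse = ", "))
  missing <- setdiff(seq_len(k), all_idx)
  if (length(missing))
    stop("landmark index unassigned (neither paired nor midline): ",
         paste(missing, collapse = ", "))
  list(pairs = pairs, midline = midline)
}

#' Read landmark configurations from a TPS file
#'
#' Parses the tpsDig/tpsUtil text dialect: records open with `LM=<k>`
#' followed by k lines of `x y` coordinates and optional `IMAGE=`,
#' `ID=`, `SCALE=` lines (keys case-insensitive; unknown keys are
#' carried through as opaque metadata). A `SCALE=` factor is multiplied
#' into the coordinates on read. Coordinates are Cartesian with y
#' increasing upward; no axis flip is applied. Parsing preserves record
#' order and tolerates CRLF line endings and trailing blank lines.
#'
#' @param path TPS file path.
#' @param classifier_table optional path to a CSV (header row) carrying
#'   classifier columns (`individual`, `side`, `image_rep`, `digit_rep`,
#'   `nest`, `location`, `species`), joined on its `id` column against
#'   the record `ID=` (preferred) or on `image` against the `IMAGE=`
#'   basename. Records without a classifier row are an error listing the
#'   unmatched keys.
#' @param symmetry_mode,pairing forwarded to [landmark_dataset()].
#' @return a `landmark_dataset`.
#' @export
read_tps <- function(path, classifier_table = NULL,
                     symmetry_mode = c("matching", "object"), pairing = NULL) {
  symmetry_mode <- match.arg(symmetry_mode)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  is_key <- function(x) grepl("^[A-Za-z][A-Za-z0-9_]*\\s*=", x)
  key_of <- function(x) toupper(sub("\\s*=.*$", "", x))
  val_of <- function(x) trimws(sub("^[^=]*=", "", x))
  recs <- list()
  i <- 1L
  n_lines <- length(lines)
  while (i <= n_lines) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; next }
    if (!is_key(ln) || key_of(ln) != "LM")
      stop("TPS parse error at line ", i, ": expected 'LM=<count>', got '", ln, "'")
    k <- suppressWarnings(as.integer(val_of(ln)))
    if (is.na(k) || k < 1L)
      stop("TPS parse error at line ", i, ": malformed LM count")
    rec_line <- i
    i <- i + 1L
    coords <- matrix(NA_real_, k, 2L)
    for (j in seq_len(k)) {
      if (i > n_lines || is_key(trimws(lines[i])))
        stop("TPS parse error in record starting at line ", rec_line,
             ": LM=", k, " but only ", j - 1L, " coordinate line(s)")
      xy <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1L]]))
      if (length(xy) != 2L || any(is.na(xy)))
        stop("TPS parse error at line ", i, ": expected 'x y' coordinates")
      coords[j, ] <- xy
      i <- i + 1L
    }
    keys <- character(); vals <- character()
    while (i <= n_lines) {
      ln <- trimws(lines[i])
      if (ln == "") { i <- i + 1L; next }
      if (!is_key(ln)) stop("TPS parse error at line ", i, ": unexpected '", ln, "'")
      if (key_of(ln) == "LM") break
      keys <- c(keys, key_of(ln)); vals <- c(vals, val_of(ln))
      i <- i + 1L
    }
    meta <- setNames(vals, keys)
    recs[[length(recs) + 1L]] <- list(k = k, coords = coords, meta = meta,
                                      line = rec_line)
  }
  if (!length(recs)) {
    return(structure(list(coords = array(0, c(0L, 2L, 0L)),
                          info = data.frame(specimen_id = character()),
                          k = 0L, symmetry_mode = symmetry_mode,
                          pairing = NULL, meta = list()),
                     class = "landmark_dataset"))
  }
  ks <- vapply(recs, `[[`, 1L, "k")
  if (length(unique(ks)) != 1L)
    stop("inconsistent landmark counts across records (k = ",
         paste(sort(unique(ks)), collapse = ", "),
         "): structures with different landmark schemes are separate datasets")
  scale_of <- function(m) {
    s <- suppressWarnings(as.numeric(m["SCALE"]))
    if (is.na(s)) 1 else s
  }
  coords <- lapply(recs, function(r) r$coords * scale_of(r$meta))
  ids <- vapply(recs, function(r) {
    id <- r$meta["ID"]
    if (!is.na(id) && nzchar(id)) return(unname(id))
    img <- r$meta["IMAGE"]
    if (!is.na(img) && nzchar(img))
      return(file_path_sans_ext(basename(unname(img))))
    NA_character_
  }, "")
  ids[is.na(ids)] <- sprintf("record%03d", which(is.na(ids)))
  info <- data.frame(specimen_id = ids, stringsAsFactors = FALSE)
  meta <- lapply(recs, function(r) r$meta[setdiff(names(r$meta), "SCALE")])
  if (!is.null(classifier_table)) {
    cls <- read.csv(classifier_table, stringsAsFactors = FALSE)
    key_col <- if ("id" %in% names(cls)) "id" else if ("image" %in% names(cls))
      "image" else stop("classifier table needs an 'id' or 'image' column")
    keys <- if (key_col == "id") ids else
      vapply(recs, function(r) {
        img <- r$meta["IMAGE"]
        if (is.na(img)) NA_character_ else file_path_sans_ext(basename(unname(img)))
      }, "")
    idx <- match(keys, cls[[key_col]])
    if (anyNA(idx))
      stop("classifier table has no row for record key(s): ",
           paste(unique(keys[is.na(idx)]), collapse = ", "))
    for (col in setdiff(names(cls), key_col)) info[[col]] <- cls[idx, col]
  }
  landmark_dataset(coords, info, symmetry_mode = symmetry_mode,
                   pairing = pairing, meta = meta)
}

#' Write a landmark dataset to a TPS file
#'
#' Emits one `LM=` record per configuration with full-precision
#' coordinates (no `SCALE=` line is written: scale is already applied),
#' an `ID=` line with the specimen id, and any opaque metadata keys.
#' With `classifier_path`, the classifier columns are written as a CSV
#' keyed on `id`, so that `read_tps(path, classifier_path)` round-trips
#' coordinates and classifiers exactly.
#'
#' @param dataset a `landmark_dataset`.
#' @param path output TPS path.
#' @param classifier_path optional output CSV path for the classifiers.
#' @return `invisible(path)`.
#' @export
write_tps <- function(dataset, path, classifier_path = NULL) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  n <- n_configs(dataset)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(n)) {
    writeLines(sprintf("LM=%d", dataset$k), con)
    xy <- dataset$coords[, , i]
    writeLines(sprintf("%.17g %.17g", xy[, 1L], xy[, 2L]), con)
    m <- if (!is.null(dataset$meta)) dataset$meta[[i]] else character()
    m <- m[setdiff(names(m), c("ID"))]
    if (length(m)) writeLines(paste0(names(m), "=", m), con)
    writeLines(sprintf("ID=%s", dataset$info$specimen_id[i]), con)
  }
  if (!is.null(classifier_path) && n > 0L) {
    cls <- dataset$info
    names(cls)[names(cls) == "specimen_id"] <- "id"
    write.csv(cls, classifier_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
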