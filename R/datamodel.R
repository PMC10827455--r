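IMAGE_EXT <- "\\.(png|jpe?g|tiff?)$"

#' Published per-class sample counts of the BreakHis collection
#'
#' The in-package copy of the published sample-distribution table: image
#' counts per class, histological subtype and magnification factor
#' (40X/100X/200X/400X). The 16 malignant cells sum to 5,429, matching the
#' stated malignant total; the benign cells sum to 2,320 while the stated
#' benign total is 2,480 - the source does not reconcile this discrepancy,
#' and this function reports the table as printed.
#'
#' @return A tibble: `class_label`, `subtype`, `magnification`, `count`.
#' @export
breakhis_table1 <- function() {
  subtypes <- c("adenosis", "fibroadenoma", "phyllodes_tumor", "tubular_adenoma",
                "ductal_carcinoma", "lobular_carcinoma", "mucinous_carcinoma",
                "papillary_carcinoma")
  counts <- rbind(
    c(114, 113, 111, 106),
    c(193, 260, 264, 137),
    c(149, 150, 140, 130),
    c(109, 121, 108, 115),
    c(864, 903, 896, 788),
    c(156, 170, 163, 137),
    c(205, 222, 196, 169),
    c(145, 142, 135, 138))
  tibble::tibble(
    class_label = rep(CLASS_LEVELS, each = 16L),
    subtype = rep(subtypes, each = 4L),
    magnification = rep(MAGNIFICATIONS, times = 8L),
    count = as.integer(t(counts))
  )
}

parse_magnification <- function(x) {
  m <- sub("^([0-9]+)[Xx]?$", "\\1", x)
  v <- suppressWarnings(as.integer(m))
  v[!v %in% MAGNIFICATIONS] <- NA_integer_
  v
}

#' Scan a BreakHis-style directory into a manifest
#'
#' Walks `root/<magnification>/<class>/[<subtype>/]<image>` and produces
#' one record per decodable image file, ordered lexicographically by path.
#' Magnification directories may be spelled `40X`, `40x` or `40`; class
#' directories must be `benign` or `malignant`. Files that are not images,
#' or that sit under unparseable directories, are skipped with a single
#' summary warning and counted in the `skipped` attribute.
#'
#' @param root dataset root directory.
#' @param layout `"mag_class"` (subtype level optional and recorded when
#'   present) or `"mag_class_subtype"` (subtype level required).
#' @return A manifest tibble: `id`, `path`, `magnification`, `class_label`,
#'   `subtype`, `split` (`"unassigned"`), `pool` (`"none"`); attribute
#'   `skipped` carries the skip count.
#' @export
scan_dataset <- function(root, layout = c("mag_class", "mag_class_subtype")) {
  layout <- match.arg(layout)
  if (!dir.exists(root)) abort(paste0("dataset root does not exist: ", root))
  rel <- sort(list.files(root, recursive = TRUE, full.names = FALSE))
  is_img <- grepl(IMAGE_EXT, rel, ignore.case = TRUE)
  skipped <- sum(!is_img)
  rel <- rel[is_img]
  rows <- purrr::map(rel, function(p) {
    parts <- strsplit(p, "/", fixed = TRUE)[[1]]
    ndir <- length(parts) - 1L
    min_dirs <- if (layout == "mag_class_subtype") 3L else 2L
    if (ndir < min_dirs) return(NULL)
    mag <- parse_magnification(parts[1])
    cls <- tolower(parts[2])
    if (is.na(mag) || !cls %in% CLASS_LEVELS) return(NULL)
    subtype <- if (ndir >= 3L) tolower(parts[3]) else "unknown"
    tibble::tibble(
      id = gsub("[/\\\\]", "_", sub(IMAGE_EXT, "", p, ignore.case = TRUE)),
      path = file.path(root, p), magnification = mag, class_label = cls,
      subtype = subtype, split = "unassigned", pool = "none")
  })
  bad <- sum(vapply(rows, is.null, TRUE))
  skipped <- skipped + bad
  if (skipped > 0L)
    warn(sprintf("skipped %d file(s) that were not parseable dataset images", skipped))
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L)
    out <- tibble::tibble(id = character(), path = character(),
                          magnification = integer(), class_label = character(),
                          subtype = character(), split = character(),
                          pool = character())
  if (anyDuplicated(out$id)) abort("duplicate record ids in scan")
  attr(out, "skipped") <- skipped
  out
}

#' Count-summary of a manifest
#'
#' Image counts per (magnification, class, subtype) plus per-class totals.
#' Every cell is non-negative and the totals equal the sums of the cells
#' by construction.
#'
#' @param manifest manifest tibble (or the published table from
#'   [breakhis_table1()], which already carries a `count` column).
#' @return An object of class `count_summary`: list with `table` (tibble:
#'   magnification, class_label, subtype, count) and `totals` (tibble:
#'   class_label, total).
#' @export
summarize_manifest <- function(manifest) {
  tab <- if ("count" %in% names(manifest)) {
    dplyr::summarise(dplyr::group_by(manifest, .data$magnification,
                                     .data$class_label, .data$subtype),
                     count = sum(.data$count), .groups = "drop")
  } else if (nrow(manifest) == 0L) {
    tibble::tibble(magnification = integer(), class_label = character(),
                   subtype = character(), count = integer())
  } else {
    dplyr::count(manifest, .data$magnification, .data$class_label,
                 .data$subtype, name = "count")
  }
  totals <- dplyr::summarise(dplyr::group_by(tab, .data$class_label),
                             total = sum(.data$count), .groups = "drop")
  structure(list(table = tab, totals = totals), class = "count_summary")
}

#' @export
print.count_summary <- function(x, ...) {
  print(x$table)
  print(x$totals)
  invisible(x)
}

#' Stratified train/test split
#'
#' Assigns each record to `train` or `test`, stratified by
#' (magnification, class): within each stratum, `round(test_fraction * n)`
#' records (round-half-up) are drawn into the test set with the given
#' seed. Deterministic given the seed; train and test are disjoint by
#' construction. Strata with fewer than 2 records trigger a warning.
#'
#' @param manifest manifest tibble.
#' @param test_fraction proportion in (0, 1); the published protocol uses
#'   0.2.
#' @param seed integer seed.
#' @return The manifest with `split` filled in.
#' @export
split_dataset <- function(manifest, test_fraction = 0.2, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1)
    abort("`test_fraction` must be strictly between 0 and 1")
  groups <- dplyr::group_split(dplyr::group_by(manifest, .data$magnification,
                                               .data$class_label))
  out <- purrr::imap(groups, function(g, gi) {
    n <- nrow(g)
    if (n < 2L) warn(sprintf("stratum with %d record(s); split assigned by rounding", n))
    n_test <- round_half_up(test_fraction * n)
    test_idx <- with_seed(derive_seed(seed, 999983, gi), sample.int(n, n_test))
    g$split <- "train"
    g$split[test_idx] <- "test"
    g
  })
  res <- dplyr::arrange(dplyr::bind_rows(out), .data$id)
  res[match(manifest$id, res$id), ]
}

#' Draw the initial labeled pool from the training split
#'
#' Marks `round(labeled_fraction * n_train)` randomly chosen training
#' records as `labeled` and the remainder as `unlabeled`; test records keep
#' `pool = "none"`. With the published 80/20 split and a 0.2 labeled
#' fraction, the labeled pool is 16% of the whole collection.
#'
#' @param manifest manifest with `split` assigned.
#' @param labeled_fraction proportion in (0, 1].
#' @param seed integer seed.
#' @return The manifest with `pool` filled in.
#' @export
sample_initial_labeled <- function(manifest, labeled_fraction = 0.2, seed = 1L) {
  if (labeled_fraction <= 0 || labeled_fraction > 1)
    abort("`labeled_fraction` must be in (0, 1]")
  if (any(manifest$split == "unassigned"))
    abort("run split_dataset() before sample_initial_labeled()")
  tr <- which(manifest$split == "train")
  n_lab <- round_half_up(labeled_fraction * length(tr))
  if (n_lab == 0L) abort("labeled pool would be empty; increase `labeled_fraction`")
  lab <- with_seed(derive_seed(seed, 413158511), sample(tr, n_lab))
  manifest$pool <- "none"
  manifest$pool[tr] <- "unlabeled"
  manifest$pool[lab] <- "labeled"
  manifest
}

#' Read / write a manifest as CSV
#'
#' @param manifest manifest tibble.
#' @param path CSV file path.
#' @return `read_manifest()` returns the manifest tibble;
#'   `write_manifest()` returns `path` invisibly.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(manifest, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(), path = readr::col_character(),
    magnification = readr::col_integer(), class_label = readr::col_character(),
    subtype = readr::col_character(), split = readr::col_character(),
    pool = readr::col_character()))
}
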