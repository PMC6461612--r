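# Atlas tables: region definitions, hemisphere labels, homotopic pairing,
# regional sizes. Every other module consults these columns instead of
# assuming any node ordering.

ATLAS_COLUMNS <- c("region_id", "name", "abbreviation", "hemisphere",
                   "homotopic_partner_id", "size_volume", "size_area")

#' Read an atlas table
#'
#' Reads a delimited (comma or tab) table with columns `region_id`, `name`,
#' `abbreviation`, `hemisphere` (L/R), `homotopic_partner_id`, `size_volume`
#' (mm^3, used for functional networks) and `size_area` (mm^2, used for
#' structural networks), and validates it: homotopic pairing must be a perfect
#' involution crossing hemispheres, abbreviations must be unique, and (unless
#' `check_n90 = FALSE`) there must be exactly 90 regions, 45 per hemisphere.
#'
#' @param path file path.
#' @param check_n90 enforce the 90-region / 45-per-hemisphere convention of
#'   the AAL cerebrum parcellation. Disable for toy atlases.
#' @return a data.frame of class `atlas_table`.
#' @export
read_atlas <- function(path, check_n90 = TRUE) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  validate_atlas(df, check_n90 = check_n90)
}

#' Validate an atlas data.frame
#'
#' @param df data.frame with the atlas columns.
#' @param check_n90 enforce 90 regions, 45 per hemisphere.
#' @return the validated data.frame, classed `atlas_table`.
#' @export
validate_atlas <- function(df, check_n90 = TRUE) {
  missing_cols <- setdiff(ATLAS_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("atlas table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[order(df$region_id), , drop = FALSE]
  rownames(df) <- NULL
  n <- nrow(df)
  if (!identical(as.integer(df$region_id), seq_len(n))) {
    stop("region_id must be 1..", n, " without gaps")
  }
  if (anyDuplicated(df$abbreviation)) {
    dup <- df$abbreviation[duplicated(df$abbreviation)][1]
    stop("duplicate abbreviation in atlas: ", dup)
  }
  if (!all(df$hemisphere %in% c("L", "R"))) {
    bad <- which(!(df$hemisphere %in% c("L", "R")))[1]
    stop("hemisphere must be 'L' or 'R' (row ", bad, ")")
  }
  if (check_n90) {
    if (n != 90) stop("atlas must have exactly 90 regions, found ", n)
    if (sum(df$hemisphere == "L") != 45) {
      stop("atlas must have 45 regions per hemisphere, found ",
           sum(df$hemisphere == "L"), " left")
    }
  } else if (sum(df$hemisphere == "L") != sum(df$hemisphere == "R")) {
    stop("atlas must have equally many regions per hemisphere")
  }
  p <- as.integer(df$homotopic_partner_id)
  if (any(p < 1 | p > n)) {
    stop("homotopic_partner_id out of range at row ", which(p < 1 | p > n)[1])
  }
  if (any(p == seq_len(n))) {
    stop("region cannot be its own homotopic partner (row ",
         which(p == seq_len(n))[1], ")")
  }
  invol <- p[p]
  if (!identical(invol, seq_len(n))) {
    bad <- which(invol != seq_len(n))[1]
    stop("homotopic pairing is not an involution: partner(partner(", bad,
         ")) = ", invol[bad])
  }
  if (any(df$hemisphere[p] == df$hemisphere)) {
    bad <- which(df$hemisphere[p] == df$hemisphere)[1]
    stop("homotopic partner of row ", bad, " is in the same hemisphere")
  }
  if (any(df$size_volume <= 0) || any(df$size_area <= 0)) {
    stop("regional sizes must be positive")
  }
  class(df) <- c("atlas_table", "data.frame")
  df
}

#' Bundled 90-region atlas
#'
#' The AAL cerebrum parcellation (90 regions, 45 per hemisphere, interleaved
#' ordering: odd indices left, even indices right, partner(2k-1) = 2k) with
#' synthetic placeholder regional sizes. The size columns are plausible
#' volumes/areas generated for testing; they are not measured values from any
#' study population.
#'
#' @return an `atlas_table` with 90 rows.
#' @export
default_atlas <- function() {
  path <- system.file("extdata", "aal90_synthetic_sizes.csv",
                      package = "hemiconn", mustWork = TRUE)
  read_atlas(path)
}

#' Region indices of one hemisphere
#'
#' @param atlas an `atlas_table`.
#' @param hemisphere "L" or "R".
#' @return integer vector of region ids, in atlas order.
#' @export
atlas_hemi_ids <- function(atlas, hemisphere = c("L", "R")) {
  hemisphere <- match.arg(hemisphere)
  atlas$region_id[atlas$hemisphere == hemisphere]
}

#' Homotopic partner map
#'
#' @param atlas an `atlas_table`.
#' @return integer vector `p` with `p[i]` the partner region id of region i.
#' @export
atlas_partner <- function(atlas) {
  as.integer(atlas$homotopic_partner_id)
}

#' Minimal interleaved atlas for an arbitrary even region count
#'
#' Builds a toy atlas with `n` regions following the interleaved convention
#' (odd left, even right, consecutive odd/even pairs homotopic) and unit-free
#' placeholder sizes. Used by the synthetic generator for non-90 region
#' counts and by tests.
#'
#' @param n even number of regions.
#' @return an `atlas_table` (90-row check relaxed unless n = 90).
#' @export
make_interleaved_atlas <- function(n) {
  if (n %% 2 != 0 || n < 4) stop("n must be an even number >= 4")
  k <- seq_len(n)
  hemi <- ifelse(k %% 2 == 1, "L", "R")
  partner <- ifelse(k %% 2 == 1, k + 1L, k - 1L)
  pair <- (k + 1L) %/% 2L
  df <- data.frame(
    region_id = k,
    name = sprintf("Region %d %s", pair, hemi),
    abbreviation = sprintf("RG%d.%s", pair, hemi),
    hemisphere = hemi,
    homotopic_partner_id = as.integer(partner),
    size_volume = 4000 + 150 * pair,
    size_area = 1200 + 40 * pair,
    stringsAsFactors = FALSE
  )
  validate_atlas(df, check_n90 = (n == 90))
}
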