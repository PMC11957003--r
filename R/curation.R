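# Dataset curation: manifest filtering and resolution-stratified splitting.
#
# A manifest is a data frame with columns map_id, model_id,
# reported_resolution; absent values are NA (encoded as empty strings in
# the TSV form).

#' Read a map/model manifest
#'
#' TSV with a header row and columns `map_id`, `model_id`,
#' `reported_resolution`; empty strings become `NA`.
#'
#' @param path TSV path.
#' @return Data frame with the three manifest columns.
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"),
                          colClasses = c(map_id = "character",
                                         model_id = "character"))
  required <- c("map_id", "model_id", "reported_resolution")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("manifest is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df$reported_resolution <- as.numeric(df$reported_resolution)
  df[required]
}

#' Write a manifest
#' @param entries manifest data frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(entries, path) {
  utils::write.table(entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Filter candidate map/model pairs
#'
#' Applies the dataset-construction rules, in order:
#' 1. drop entries without an associated atomic model (`model_id` absent);
#' 2. drop entries without a reported resolution;
#' 3. drop entries whose resolution lies outside `[min_res, max_res]`
#'    (bounds inclusive; defaults 1-4 Å, the high-resolution regime);
#' 4. among entries sharing a `model_id`, keep only the one with the best
#'    (smallest) resolution, ties broken by lexicographic `map_id`.
#'
#' @param entries manifest data frame (see [read_manifest()]); `map_id`
#'   values must be unique.
#' @param min_res,max_res inclusive resolution bounds in Å.
#' @return List with `kept` (surviving entries, original order) and
#'   `rejected`, a named integer vector of per-rule counts
#'   (`no_model`, `no_resolution`, `resolution_out_of_range`, `redundant`).
#' @export
filter_manifest <- function(entries, min_res = 1.0, max_res = 4.0) {
  if (anyDuplicated(entries$map_id))
    stop("manifest error: duplicate map_id values", call. = FALSE)

  no_model <- is.na(entries$model_id) | entries$model_id == ""
  pool <- entries[!no_model, , drop = FALSE]
  no_res <- is.na(pool$reported_resolution)
  pool2 <- pool[!no_res, , drop = FALSE]
  out_of_range <- pool2$reported_resolution < min_res |
    pool2$reported_resolution > max_res
  pool3 <- pool2[!out_of_range, , drop = FALSE]

  # best-resolution map per model, lexicographic map_id breaking ties
  ord <- order(pool3$model_id, pool3$reported_resolution, pool3$map_id)
  sorted <- pool3[ord, , drop = FALSE]
  winners <- sorted$map_id[!duplicated(sorted$model_id)]
  redundant <- nrow(pool3) - length(winners)
  kept <- pool3[pool3$map_id %in% winners, , drop = FALSE]
  rownames(kept) <- NULL

  list(kept = kept,
       rejected = c(no_model = sum(no_model),
                    no_resolution = sum(no_res),
                    resolution_out_of_range = sum(out_of_range),
                    redundant = redundant))
}

#' Resolution-stratified train/val/test split
#'
#' Bins entries by reported resolution, then assigns entries within each
#' bin to splits by a seeded deterministic shuffle, with split sizes chosen
#' by the largest-remainder rule so that fractions are respected per bin.
#' Splitting by resolution (rather than at random) keeps the resolution
#' distribution comparable across train, validation and test sets.
#'
#' @param entries manifest data frame with `reported_resolution` present for
#'   every row.
#' @param bin_edges resolution bin edges in Å (as for [cut()]; lowest edge
#'   inclusive).
#' @param fractions named numeric vector of split fractions summing to 1,
#'   e.g. `c(train = 0.8, val = 0.1, test = 0.1)`.
#' @param seed integer seed for the shuffle.
#' @return `entries` with an added `split` column; every entry lands in
#'   exactly one split. Empty bins are skipped with a warning.
#' @export
split_by_resolution <- function(entries, bin_edges = c(1, 2, 3, 4),
                                fractions = c(train = 0.8, val = 0.1,
                                              test = 0.1),
                                seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1", call. = FALSE)
  if (anyNA(entries$reported_resolution))
    stop("every entry needs a reported_resolution to be split", call. = FALSE)
  bins <- cut(entries$reported_resolution, breaks = bin_edges,
              include.lowest = TRUE)
  if (anyNA(bins))
    stop("some resolutions fall outside bin_edges", call. = FALSE)

  # largest-remainder apportionment of n entries to the fractions
  apportion <- function(n) {
    raw <- n * fractions
    base <- floor(raw)
    left <- n - sum(base)
    if (left > 0) {
      extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
      base[extra] <- base[extra] + 1
    }
    base
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  split <- character(nrow(entries))
  for (b in levels(bins)) {
    rows <- which(bins == b)
    if (!length(rows)) {
      warning("empty resolution bin ", b, " skipped", call. = FALSE)
      next
    }
    sizes <- apportion(length(rows))
    shuffled <- rows[sample.int(length(rows))]
    split[shuffled] <- rep(names(fractions), times = sizes)
  }
  entries$split <- split
  entries
}
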