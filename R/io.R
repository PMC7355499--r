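# Plain-text I/O: LAT CSV tables, probability reports, path and
# localization JSON. All ids are 1-based in files.

#' Read / write LAT tables as CSV
#'
#' The CSV schema is long-format with columns `activation_id`,
#' `pair_index`, `loop`, `lat_ms`. Round-trips are lossless to 1e-9 ms.
#'
#' @param path file path.
#' @param lat an [activation_matrix()].
#' @return `read_lat_csv()` returns an `activation_matrix`;
#'   `write_lat_csv()` returns `path` invisibly.
#' @export
read_lat_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("activation_id", "pair_index", "loop", "lat_ms")
  if (!all(need %in% names(df))) {
    stop("LAT CSV format error: expected columns ",
         paste(need, collapse = ", "))
  }
  bad <- which(!df$pair_index %in% PAIR_INDEX_ALL)
  if (length(bad)) {
    stop("LAT CSV format error: unknown pair_index '", df$pair_index[bad[1]],
         "' at row ", bad[1])
  }
  want_loop <- ifelse(df$pair_index <= 9, "inner", "outer")
  bad <- which(df$loop != want_loop)
  if (length(bad)) {
    stop("LAT CSV format error: loop label '", df$loop[bad[1]],
         "' inconsistent with pair_index ", df$pair_index[bad[1]],
         " at row ", bad[1])
  }
  ids <- sort(unique(df$activation_id))
  m <- matrix(NA_real_, length(ids), 10,
              dimnames = list(ids, as.character(PAIR_INDEX_ALL)))
  m[cbind(match(df$activation_id, ids), match(df$pair_index, PAIR_INDEX_ALL))] <-
    df$lat_ms
  activation_matrix(m, activation_ids = ids)
}

#' @rdname read_lat_csv
#' @export
write_lat_csv <- function(lat, path) {
  lat <- activation_matrix(lat, activation_ids = rownames(lat))
  loops <- pair_loops(lat)
  df <- expand.grid(activation_id = rownames(lat),
                    pair_index = as.integer(colnames(lat)),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$loop <- loops[as.character(df$pair_index)]
  df$lat_ms <- as.numeric(lat[cbind(df$activation_id,
                                    as.character(df$pair_index))])
  df <- df[order(match(df$activation_id, rownames(lat)), df$pair_index), ]
  df$lat_ms <- formatC(df$lat_ms, digits = 15, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a probability report CSV
#'
#' One row per loop, pair and mode with the fitted probability, EL bounds
#' and raw/reported p-values.
#'
#' @param probs the `probabilities` table of a [focalfit()] (or the fit).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probability_csv <- function(probs, path) {
  if (inherits(probs, "focalfit")) probs <- probs$probabilities
  utils::write.csv(probs, path, row.names = FALSE)
  invisible(path)
}

#' Write paths / localization reports as JSON
#'
#' @param fit a [focalfit()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_paths_json <- function(fit, path) {
  stopifnot(inherits(fit, "focalfit"))
  entries <- attr(fit$paths, "entries")
  per_source <- lapply(seq_len(nrow(fit$paths)), function(r) {
    m <- fit$matched[[r]]
    list(source_rank = r,
         path = as.list(fit$paths[r, c("FO", "FI", "LI", "LO")]),
         entries = entries[entries$source_rank == r, ],
         T_star = if (is.null(m)) 0L else m$T_star)
  })
  jsonlite::write_json(per_source, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_paths_json
#' @param loc a `focal_localization` (from [predict.focalfit()]) or a list
#'   of `localization_result` objects.
#' @export
write_localization_json <- function(loc, path) {
  out <- lapply(seq_along(loc), function(r) {
    x <- loc[[r]]
    if (is.null(x)) return(list(source_rank = r, localized = FALSE))
    list(source_rank = r, localized = TRUE,
         path = x$path, T_star = x$T_star, replicates = x$replicates,
         point_estimate = x$point_estimate, vertex = x$vertex,
         dispersion = x$dispersion,
         cv_mean = mean(x$cv_draws), cv_sd = stats::sd(x$cv_draws),
         locations = x$locations)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Worked-example activation-probability tables
#'
#' Loads the packaged worked-example probability vectors (two case studies
#' of first/last activation probabilities for both catheter loops, as
#' produced by the constrained multinomial MLE) used in examples and in the
#' acceptance checks.
#'
#' @param case `1` (two well-separated sources) or `2` (an ectopic trigger
#'   adjacent to the normal source).
#' @return data frame with columns `loop`, `pair_index`, `mode`, `p_star`
#'   and `p_value` (recomputed raw p-values via [activation_pvalue()]).
#' @export
worked_example_probs <- function(case = 1) {
  file <- system.file("extdata",
                      sprintf("case_study_%d_probabilities.csv", case),
                      package = "focalmap")
  if (file == "") stop("unknown case study: ", case)
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  df$p_value <- activation_pvalue(df$p_star, D = 5)
  df$p_reported <- report_pvalue(df$p_value)
  df
}
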