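# Source counting and most-probable-path extraction.

#' Infer the number of electrical sources
#'
#' Counts the significant pairs (raw p-value below `alpha`) in each of the
#' four probability vectors (first/last x inner/outer) and returns the
#' maximum. The maximum rule lets a source that is visible only in, say,
#' the last-activation probabilities (because both sources enter a loop
#' through the same pair) still be counted. If no vector has a significant
#' pair the count falls back to 1 with a low-confidence warning.
#'
#' @param probs activation-probability data frame (columns `loop`,
#'   `pair_index`, `mode`, `p_star`, `p_value`).
#' @param alpha significance level (default 0.1).
#' @return integer source count (>= 1).
#' @export
infer_source_count <- function(probs, alpha = 0.1) {
  sig <- significant_pairs(probs, alpha)
  n <- max(vapply(sig, length, integer(1)))
  if (n == 0L) {
    warning("no significant activation probabilities; assuming a single ",
            "source (low confidence)")
    return(1L)
  }
  as.integer(n)
}

#' Extract most probable wave paths
#'
#' A path for source rank `r` is the 4-tuple `(FO, FI, LI, LO)`: the pair
#' with the `r`-th largest first-activation probability in the outer loop,
#' then in the inner loop, then the `r`-th largest last-activation
#' probability in the inner and outer loops. Ranks are paired positionally
#' (largest with largest). Ties are broken toward the smaller pair index.
#'
#' For ranks beyond 1, a candidate entry is kept only when its probability
#' reaches the uniform level `1/D`; otherwise the wave is taken to share
#' the rank-1 entry for that vector (two sources whose waves enter a loop
#' through the same pair). Entries whose p-value is not below `alpha` are
#' flagged `significant = FALSE` in the attached entry table.
#'
#' @param probs activation-probability data frame (see [focalfit()]).
#' @param n_sources number of paths to extract; default
#'   [infer_source_count()].
#' @param alpha significance level used for flagging entries.
#' @return data frame of class `probable_paths` with columns `source_rank`,
#'   `FO`, `FI`, `LI`, `LO`, and attribute `entries` (per-entry probability,
#'   p-value, shared and significance flags).
#' @export
extract_probable_paths <- function(probs, n_sources = NULL, alpha = 0.1) {
  D <- max(table(paste(probs$loop, probs$mode)))
  n_sources <- n_sources %||% suppressWarnings(infer_source_count(probs, alpha))
  if (n_sources > D) stop("'n_sources' cannot exceed the pairs per loop")
  slots <- list(FO = c("first", "outer"), FI = c("first", "inner"),
                LI = c("last", "inner"), LO = c("last", "outer"))
  paths <- data.frame(source_rank = seq_len(n_sources))
  entries <- list()
  for (nm in names(slots)) {
    sub <- probs[probs$mode == slots[[nm]][1] & probs$loop == slots[[nm]][2], ]
    sub <- sub[order(-sub$p_star, sub$pair_index), ]
    col <- integer(n_sources)
    for (r in seq_len(n_sources)) {
      shared <- r > 1L && sub$p_star[r] < 1 / D
      use <- if (shared) 1L else r
      col[r] <- sub$pair_index[use]
      entries[[length(entries) + 1L]] <- data.frame(
        source_rank = r, entry = nm, pair_index = sub$pair_index[use],
        p_star = sub$p_star[use], p_value = sub$p_value[use],
        shared = shared, significant = sub$p_value[use] < alpha
      )
    }
    paths[[nm]] <- col
  }
  attr(paths, "entries") <- do.call(rbind, entries)
  class(paths) <- c("probable_paths", class(paths))
  paths
}

#' @export
print.probable_paths <- function(x, ...) {
  cat("Most probable wave paths (FO-FI-LI-LO):\n")
  for (r in seq_len(nrow(x))) {
    cat(sprintf("  source %d: %d-%d-%d-%d\n", x$source_rank[r],
                x$FO[r], x$FI[r], x$LI[r], x$LO[r]))
  }
  e <- attr(x, "entries")
  if (!is.null(e) && any(!e$significant)) {
    bad <- e[!e$significant, ]
    cat("  note: non-significant entries:",
        paste(sprintf("rank %d %s (pair %d, p = %.2f)", bad$source_rank,
                      bad$entry, bad$pair_index, bad$p_value), collapse = "; "),
        "\n")
  }
  invisible(x)
}

#' Select activations consistent with a path
#'
#' Keeps the activations whose observed first/last pattern matches the
#' path: under `"outer_only"` strictness the outer loop's first pair must
#' equal `FO` and its last pair `LO`; under `"full"` the inner-loop entries
#' `FI` and `LI` must match as well.
#'
#' @param lat an [activation_matrix()].
#' @param path one row of an [extract_probable_paths()] result (or any list
#'   with elements `FO`, `FI`, `LI`, `LO`).
#' @param strictness `"outer_only"` (default) or `"full"`.
#' @return list of class `path_matched`: `path`, `activation_ids`
#'   (character row ids), `rows` (row positions), `T_star`.
#' @export
filter_path_matched <- function(lat, path,
                                strictness = c("outer_only", "full")) {
  strictness <- match.arg(strictness)
  lat <- activation_matrix(lat, activation_ids = rownames(lat))
  firsts <- compute_indicators(lat, "first")
  lasts <- compute_indicators(lat, "last")
  pick <- function(z) {
    stats::setNames(as.integer(colnames(z))[apply(z, 1, which.max)],
                    rownames(z))
  }
  fo <- pick(firsts$outer); lo <- pick(lasts$outer)
  ids <- intersect(names(fo), names(lo))
  ok <- fo[ids] == path$FO & lo[ids] == path$LO
  if (strictness == "full") {
    fi <- pick(firsts$inner); li <- pick(lasts$inner)
    ids <- Reduce(intersect, list(ids, names(fi), names(li)))
    ok <- ok[ids] & fi[ids] == path$FI & li[ids] == path$LI
  }
  rows <- match(ids[ok], rownames(lat))
  if (length(rows) == 0L) {
    stop("no activation matches the path ", path$FO, "-", path$FI, "-",
         path$LI, "-", path$LO,
         "; collect more activations or try a different path")
  }
  structure(list(path = as.list(path)[c("FO", "FI", "LI", "LO")],
                 activation_ids = rownames(lat)[rows],
                 rows = rows, T_star = length(rows)),
            class = "path_matched")
}
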