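# Metrics for comparing posterior decodings and CNV calls, plus the plain
# text formats: probe tables in, BED-like calls and posterior tables out.

flatten_marginals <- function(p) {
  if (is.list(p) && !is.matrix(p)) do.call(rbind, p) else as.matrix(p)
}

#' Average posterior error between two decodings
#'
#' `(1 / 2T) * sum_t sum_i | P_est(q_t = i) - P_ref(q_t = i) |`: the
#' total-variation distance between per-position state posteriors, averaged
#' over positions.  Lies in \[0, 1\] and is symmetric.
#'
#' @param p_est,p_ref T x N matrices of per-position state distributions
#'   (or per-chromosome lists of them, pooled by concatenation).
#' @return The average posterior error.
#' @export
average_posterior_error <- function(p_est, p_ref) {
  a <- flatten_marginals(p_est)
  b <- flatten_marginals(p_ref)
  if (!all(dim(a) == dim(b))) stop("posterior arrays must match in shape")
  sum(abs(a - b)) / (2 * nrow(a))
}

#' Hamming distance between two state paths
#'
#' @param path_a,path_b Integer vectors (or per-chromosome lists) of equal
#'   total length.
#' @return Number of mismatching positions.
#' @export
viterbi_mismatch <- function(path_a, path_b) {
  a <- unlist(path_a, use.names = FALSE)
  b <- unlist(path_b, use.names = FALSE)
  if (length(a) != length(b)) stop("paths must have equal length")
  sum(a != b)
}

cnv_classes <- c("loss", "neutral", "gain")

as_class_vector <- function(x) {
  v <- if (inherits(x, "call_set")) unlist(x$classes, use.names = FALSE)
       else unlist(x, use.names = FALSE)
  if (!all(v %in% cnv_classes))
    stop("classes must be in {loss, neutral, gain}")
  v
}

#' Two-class precision/recall/F1 of CNV calls
#'
#' Aberrant probes (loss or gain) form the positive class, neutral probes
#' the negative class.  `recall = tp/(tp+fn)`, `precision = tp/(tp+fp)`,
#' `F1 = 2 * recall * precision / (recall + precision)`.  Ratios with zero
#' denominators are returned as `NA` (flagged, not coerced to 0).
#'
#' @param calls,truth Per-probe classes (`call_set` objects, vectors, or
#'   per-chromosome lists) over the same probes.
#' @return List with `f1`, `recall`, `precision`, `tp`, `fp`, `tn`, `fn`.
#' @export
two_class_metrics <- function(calls, truth) {
  cv <- as_class_vector(calls)
  tv <- as_class_vector(truth)
  if (length(cv) != length(tv)) stop("calls and truth must match in length")
  cp <- cv != "neutral"; tp_ <- tv != "neutral"
  tp <- sum(cp & tp_); fp <- sum(cp & !tp_)
  fn <- sum(!cp & tp_); tn <- sum(!cp & !tp_)
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(recall) && !is.na(precision) && recall + precision > 0)
    2 * recall * precision / (recall + precision) else NA_real_
  list(f1 = f1, recall = recall, precision = precision,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Three-class confusion matrix
#'
#' Rows are indexed by the truth class, columns by the called class, in the
#' order loss, neutral, gain; each row is normalized to sum 1 (rows with no
#' truth probes are NA).
#'
#' @inheritParams two_class_metrics
#' @return 3 x 3 row-normalized matrix.
#' @export
confusion_matrix3 <- function(calls, truth) {
  cv <- factor(as_class_vector(calls), levels = cnv_classes)
  tv <- factor(as_class_vector(truth), levels = cnv_classes)
  if (length(cv) != length(tv)) stop("calls and truth must match in length")
  tab <- table(truth = tv, call = cv)
  m <- unclass(tab / rowSums(tab))
  m[, , drop = FALSE]
}

runs_to_segments <- function(classes_list, marg_list = NULL,
                             class_mass = NULL) {
  do.call(rbind, lapply(names(classes_list), function(ch) {
    cls <- classes_list[[ch]]
    r <- rle(cls)
    end <- cumsum(r$lengths)
    start <- end - r$lengths
    mp <- rep(NA_real_, length(r$lengths))
    if (!is.null(marg_list)) {
      cm <- class_mass[[ch]]
      for (k in seq_along(r$lengths))
        mp[k] <- mean(cm[cbind((start[k] + 1):end[k],
                               match(r$values[k], cnv_classes))])
    }
    data.frame(chrom = ch, start = start, end = end, class = r$values,
               mean_posterior = mp, stringsAsFactors = FALSE)
  }))
}

#' CNV calls from a chain's averaged posteriors
#'
#' Averages per-probe posterior marginals over the chain's trailing window
#' (already stored in the chain), sums the mass of the states mapped to
#' each class, and calls each probe's class by the argmax; ties are broken
#' toward neutral.  Runs of equal class become segments.
#'
#' @param chain An `fbg_chain` with posterior marginals.
#' @param state_to_class Character vector, one of loss/neutral/gain per HMM
#'   state (e.g. `c("loss", "neutral", "gain", "gain")` for a 4-state
#'   model).
#' @return An object of class `call_set`: `classes` (per-chromosome
#'   vectors) and `segments` (BED-like data frame with 0-based half-open
#'   probe coordinates and the mean posterior of the called class).
#' @export
calls_from_chain <- function(chain, state_to_class) {
  stopifnot(!is.null(chain$posterior_mean_marginals),
            all(state_to_class %in% cnv_classes))
  class_mass <- lapply(chain$posterior_mean_marginals, function(g) {
    cm <- vapply(cnv_classes, function(cl) {
      sel <- which(state_to_class == cl)
      if (length(sel) == 0) rep(0, nrow(g)) else rowSums(g[, sel, drop = FALSE])
    }, numeric(nrow(g)))
    matrix(cm, nrow = nrow(g), dimnames = list(NULL, cnv_classes))
  })
  classes <- lapply(class_mass, function(cm) {
    vapply(seq_len(nrow(cm)), function(t) {
      mx <- max(cm[t, ])
      cand <- cnv_classes[cm[t, ] >= mx - 1e-12]
      if ("neutral" %in% cand) "neutral" else cand[1]
    }, "")
  })
  structure(list(classes = classes,
                 segments = runs_to_segments(classes,
                                             chain$posterior_mean_marginals,
                                             class_mass),
                 state_to_class = state_to_class),
            class = "call_set")
}

#' @export
print.call_set <- function(x, ...) {
  n <- sum(lengths(x$classes))
  ab <- sum(unlist(x$classes) != "neutral")
  cat(sprintf("CNV call set: %d probes, %d aberrant, %d segments\n",
              n, ab, nrow(x$segments)))
  invisible(x)
}

#' Read a probe table
#'
#' Tab-delimited with a header; columns `chrom`, `position`, `value` (the
#' `position` column may be absent).  Rows are grouped by chromosome in
#' order of first appearance.
#'
#' @param path File path.
#' @return An `observation_track`.
#' @export
read_probe_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "value") %in% names(df)))
    stop("probe table needs 'chrom' and 'value' columns")
  bad <- which(!is.finite(df$value))
  if (length(bad))
    stop("malformed value at line ", bad[1] + 1L)
  chroms <- unique(df$chrom)
  values <- lapply(chroms, function(ch) df$value[df$chrom == ch])
  names(values) <- chroms
  positions <- NULL
  if ("position" %in% names(df)) {
    positions <- lapply(chroms, function(ch) df$position[df$chrom == ch])
    names(positions) <- chroms
  }
  observation_track(values, positions)
}

#' Write a probe table
#' @param track An `observation_track`.
#' @param path Output path.
#' @export
write_probe_table <- function(track, path) {
  df <- do.call(rbind, lapply(names(track$observations), function(ch) {
    v <- track$observations[[ch]]
    pos <- if (!is.null(track$positions)) track$positions[[ch]]
           else seq_along(v) - 1L
    data.frame(chrom = ch, position = pos, value = v,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write CNV calls as a BED-like table
#'
#' Columns: chrom, start, end (0-based half-open probe indices), class,
#' mean posterior of the called class over the segment.
#'
#' @param calls A `call_set`.
#' @param path Output path.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls$segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Write per-probe posterior marginals
#'
#' One row per probe: chrom, probe index (0-based), one column per state.
#'
#' @param chain An `fbg_chain`.
#' @param path Output path.
#' @export
write_posteriors <- function(chain, path) {
  df <- do.call(rbind, lapply(names(chain$posterior_mean_marginals),
                              function(ch) {
    g <- chain$posterior_mean_marginals[[ch]]
    out <- data.frame(chrom = ch, index = seq_len(nrow(g)) - 1L)
    for (i in seq_len(ncol(g))) out[[paste0("state", i)]] <- g[, i]
    out
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write the parameter trace of a chain
#'
#' Line-delimited records: iteration, flattened means, variances, A, pi.
#'
#' @param chain An `fbg_chain`.
#' @param path Output path.
#' @export
write_chain_dump <- function(chain, path) {
  rows <- lapply(seq_len(chain$M), function(m) {
    th <- chain$draws[[m]]
    c(iteration = m,
      stats::setNames(th$means, paste0("mu", seq_len(th$N))),
      stats::setNames(th$variances, paste0("var", seq_len(th$N))),
      stats::setNames(as.vector(t(th$A)),
                      paste0("a", rep(seq_len(th$N), each = th$N),
                             rep(seq_len(th$N), th$N))),
      stats::setNames(th$pi, paste0("pi", seq_len(th$N))))
  })
  df <- as.data.frame(do.call(rbind, rows))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
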