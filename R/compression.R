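# kd-tree style compression of an observation sequence into blocks that
# store (count, sum of values, sum of squares).  The recursion alternates a
# value split (around the median) with a positional split (at the largest
# gap between consecutive observations), emitting a block whenever the value
# range of the current segment falls below a level-dependent threshold.

# Allowed block width at recursion level L: starts at w for L = 1 and
# shrinks by a factor delta per level.  Isolated here because the exponent
# convention is the one genuinely tunable reading of the stop rule.
level_width <- function(w, delta, L) w / delta^(L - 1)

#' Compress an observation sequence into moment-summarized blocks
#'
#' Recursive block construction: a segment is emitted as one block when its
#' value range falls below the level-shrinking width threshold (or when it
#' has a single observation).  Otherwise it is split -- alternately around
#' the median value (into maximal consecutive runs lying entirely on one
#' side, level advances) and at the largest gap between consecutive values
#' (level unchanged).  Emitted blocks preserve the original order and tile
#' the sequence.
#'
#' @param obs Numeric observation vector.
#' @param w Width parameter, in observation units; `w = 0` yields
#'   all-singleton blocks for distinct values.
#' @param delta Per-level width shrink factor (default 1.25).
#' @return A block list with fields `start` (1-based first index), `count`,
#'   `sum1`, `sum2`, ordered and tiling `obs`.
#' @export
kd_compress <- function(obs, w, delta = 1.25) {
  if (length(obs) < 1) stop("observation sequence must be nonempty")
  if (w < 0) stop("width must be nonnegative")
  obs <- as.numeric(obs)
  Tn <- length(obs)
  starts <- integer(0)
  ends <- integer(0)
  max_depth <- 0L
  depth <- 0L
  emit <- function(lo, hi) {
    starts[[length(starts) + 1L]] <<- lo
    ends[[length(ends) + 1L]] <<- hi
  }
  recurse <- function(lo, hi, L, d) {
    depth <<- depth + 1L
    on.exit(depth <<- depth - 1L)
    if (depth > max_depth) max_depth <<- depth
    if (hi == lo) { emit(lo, hi); return(invisible()) }
    seg <- obs[lo:hi]
    rng <- max(seg) - min(seg)
    if (rng < level_width(w, delta, L)) { emit(lo, hi); return(invisible()) }
    if (rng == 0) {
      # all values identical but the threshold is not met (w = 0): the
      # recursion would peel off one observation at a time; emit the
      # identical singletons it converges to directly
      for (k in lo:hi) emit(k, k)
      return(invisible())
    }
    if (d == 1L) {
      sv <- sort(seg)
      med <- sv[(length(sv) + 1L) %/% 2L]  # lower median
      side <- sign(seg - med)
      # ties (side == 0) attach to the run in progress; leading ties join
      # the first run
      nz <- which(side != 0)
      if (length(nz) == 0) {
        recurse(lo, hi, L + 1L, 0L)
      } else {
        filled <- side
        first_nz <- nz[1]
        if (first_nz > 1) filled[1:(first_nz - 1)] <- side[first_nz]
        for (k in seq_along(filled)[-1])
          if (filled[k] == 0) filled[k] <- filled[k - 1]
        run_starts <- c(1L, which(diff(filled) != 0) + 1L)
        run_ends <- c(run_starts[-1] - 1L, length(seg))
        for (r in seq_along(run_starts))
          recurse(lo + run_starts[r] - 1L, lo + run_ends[r] - 1L, L + 1L, 0L)
      }
    } else {
      gaps <- abs(diff(seg))
      cut <- which.max(gaps)  # leftmost largest gap
      recurse(lo, lo + cut - 1L, L, 1L)
      recurse(lo + cut, hi, L, 1L)
    }
    invisible()
  }
  recurse(1L, Tn, 1L, 1L)
  starts <- unlist(starts)
  ends <- unlist(ends)
  res <- make_blocks(obs, starts, ends)
  attr(res, "max_depth") <- max_depth
  res
}

make_blocks <- function(obs, starts, ends) {
  list(start = starts,
       count = ends - starts + 1L,
       sum1 = vapply(seq_along(starts),
                     function(k) sum(obs[starts[k]:ends[k]]), 0),
       sum2 = vapply(seq_along(starts),
                     function(k) sum(obs[starts[k]:ends[k]]^2), 0))
}

block_means <- function(blocks) blocks$sum1 / blocks$count

add_blocks <- function(blocks, ks) {
  list(start = blocks$start[ks[1]],
       count = sum(blocks$count[ks]),
       sum1 = sum(blocks$sum1[ks]),
       sum2 = sum(blocks$sum2[ks]))
}

#' Merge adjacent compressed blocks
#'
#' Single left-to-right pass over an ordered block list.  At each position
#' the pair rule is checked first: blocks a, b merge when their means
#' differ by less than `w`.  Failing that, the triple rule: blocks a, b, c
#' merge when the outer means differ by less than `w` and the inner block
#' holds a single observation.  A merged block does not take part in
#' further merging (one pass, no iteration to fixpoint).  Moments add
#' exactly; the output still tiles the sequence.
#'
#' @param blocks Block list as returned by [kd_compress()].
#' @param w Width parameter.
#' @return Merged block list.
#' @export
merge_blocks <- function(blocks, w) {
  nb <- length(blocks$start)
  if (nb <= 1) return(blocks)
  out_start <- integer(0); out_count <- integer(0)
  out_sum1 <- numeric(0); out_sum2 <- numeric(0)
  push <- function(b) {
    out_start[[length(out_start) + 1L]] <<- b$start
    out_count[[length(out_count) + 1L]] <<- b$count
    out_sum1[[length(out_sum1) + 1L]] <<- b$sum1
    out_sum2[[length(out_sum2) + 1L]] <<- b$sum2
  }
  at <- function(i) list(start = blocks$start[i], count = blocks$count[i],
                         sum1 = blocks$sum1[i], sum2 = blocks$sum2[i])
  fuse <- function(a, b) list(start = a$start, count = a$count + b$count,
                              sum1 = a$sum1 + b$sum1, sum2 = a$sum2 + b$sum2)
  mean_at <- function(i) blocks$sum1[i] / blocks$count[i]
  i <- 1L
  while (i <= nb) {
    if (i + 1L <= nb && abs(mean_at(i) - mean_at(i + 1L)) < w) {
      push(fuse(at(i), at(i + 1L)))
      i <- i + 2L
    } else if (i + 2L <= nb && blocks$count[i + 1L] == 1L &&
               abs(mean_at(i) - mean_at(i + 2L)) < w) {
      push(fuse(fuse(at(i), at(i + 1L)), at(i + 2L)))
      i <- i + 3L
    } else {
      push(at(i))
      i <- i + 1L
    }
  }
  list(start = out_start, count = out_count, sum1 = out_sum1, sum2 = out_sum2)
}

#' Compress a whole track
#'
#' Runs [kd_compress()] followed by [merge_blocks()] on every chromosome.
#'
#' @param track An `observation_track`.
#' @param w Width parameter in observation units (use multiples of
#'   `track$sigma_D` to follow the usual convention).
#' @param delta Per-level width shrink factor.
#' @return An object of class `compressed_track`: per-chromosome block
#'   lists plus `total_blocks`, `total_obs`, `gamma = T'/T`, and
#'   `width_used`.
#' @export
compress_track <- function(track, w, delta = 1.25) {
  blocks <- lapply(track$observations, function(o)
    merge_blocks(kd_compress(o, w, delta), w))
  tb <- sum(vapply(blocks, function(b) length(b$count), 0L))
  To <- track_length(track)
  structure(list(blocks = blocks, total_blocks = tb, total_obs = To,
                 gamma = tb / To, width_used = w, delta = delta),
            class = "compressed_track")
}

#' @export
print.compressed_track <- function(x, ...) {
  cat(sprintf("Compressed track: %d blocks / %d obs (gamma = %.4g), w = %.4g\n",
              x$total_blocks, x$total_obs, x$gamma, x$width_used))
  invisible(x)
}

#' Block table of a compressed track
#'
#' @param ct A `compressed_track`.
#' @return A data frame with one row per block: `chrom`, `start`, `end`
#'   (0-based half-open observation indices), `count`, `mean`, `variance`.
#' @export
block_table <- function(ct) {
  do.call(rbind, lapply(names(ct$blocks), function(ch) {
    b <- ct$blocks[[ch]]
    m <- block_means(b)
    data.frame(chrom = ch, start = b$start - 1L,
               end = b$start - 1L + b$count, count = b$count,
               mean = m, variance = pmax(b$sum2 / b$count - m^2, 0),
               stringsAsFactors = FALSE)
  }))
}

#' Compression ratio as a function of width
#'
#' @param track An `observation_track`.
#' @param widths Numeric grid of widths (observation units).
#' @param delta Per-level width shrink factor.
#' @return Data frame with columns `w` and `gamma` (blocks over
#'   observations, pooled across chromosomes, merging included).
#' @export
compression_curve <- function(track, widths, delta = 1.25) {
  if (length(widths) < 1 || any(widths < 0))
    stop("widths must be a nonempty nonnegative grid")
  data.frame(w = widths,
             gamma = vapply(widths, function(w)
               compress_track(track, w, delta)$gamma, 0))
}

#' Default width grid in multiples of sigma_D
#'
#' @param sigma_D Pooled standard deviation of the observations.
#' @param from,to,by Grid of multipliers (defaults 0.25 to 4 in steps of
#'   0.25).
#' @return Numeric widths `sigma_D * seq(from, to, by)`.
#' @export
default_width_grid <- function(sigma_D, from = 0.25, to = 4, by = 0.25) {
  sigma_D * seq(from, to, by = by)
}

#' Knee of the compression curve (L-method)
#'
#' Fits least-squares lines to the left and right parts of the (w, gamma)
#' curve for every admissible split and picks the split minimizing the
#' count-weighted total RMSE; the split point is shared by both lines and
#' its width is the knee.  A split adjacent to either boundary (as happens on a straight
#' line, where no knee exists) is flagged low-confidence.
#'
#' @param curve Data frame with columns `w` and `gamma`, at least 4 rows.
#' @return List with `w` (the knee), `split` (index into `curve`),
#'   `rmse`, and `low_confidence`.
#' @export
select_width_lmethod <- function(curve) {
  n <- nrow(curve)
  if (is.null(n) || n < 4) stop("the L-method needs at least 4 curve points")
  x <- curve$w; y <- curve$gamma
  fit_rmse <- function(idx) {
    f <- stats::lm.fit(cbind(1, x[idx]), y[idx])
    sqrt(mean(f$residuals^2))
  }
  # the candidate knee point belongs to both lines
  cands <- 2:(n - 1)
  total <- vapply(cands, function(c) {
    (c / (n + 1)) * fit_rmse(1:c) +
      ((n - c + 1) / (n + 1)) * fit_rmse(c:n)
  }, 0)
  c_best <- cands[which.min(total)]
  # a knee is only credible if two lines fit distinctly better than one
  rmse_one <- fit_rmse(seq_len(n))
  list(w = x[c_best], split = c_best, rmse = min(total),
       low_confidence = c_best == cands[1] || c_best == cands[length(cands)] ||
         rmse_one <= 1.05 * min(total) + 1e-12)
}

#' Validate a compressed track against its source
#'
#' Checks tiling (contiguous, ordered, covering blocks) and moment
#' conservation against the raw observations.
#'
#' @param ct A `compressed_track`.
#' @param track The `observation_track` it was built from.
#' @param tol Relative tolerance for moment conservation.
#' @return `TRUE` invisibly; stops with a message otherwise.
#' @export
validate_compression <- function(ct, track, tol = 1e-9) {
  for (ch in names(ct$blocks)) {
    b <- ct$blocks[[ch]]
    o <- track$observations[[ch]]
    if (b$start[1] != 1L ||
        !all(b$start[-1] == b$start[-length(b$start)] +
               b$count[-length(b$count)]) ||
        sum(b$count) != length(o))
      stop("blocks do not tile chromosome ", ch)
    relerr <- function(a, bb) abs(a - bb) / max(1, abs(bb))
    if (relerr(sum(b$sum1), sum(o)) > tol ||
        relerr(sum(b$sum2), sum(o^2)) > tol)
      stop("block moments do not conserve totals on chromosome ", ch)
    if (any(b$sum2 - b$sum1^2 / b$count < -1e-9 * pmax(1, b$sum2)))
      stop("Cauchy-Schwarz violated on chromosome ", ch)
  }
  invisible(TRUE)
}
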