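# Tandem-repeat detection for control regions by exhaustive scan. Control
# regions are short (<= ~2.4 kb), so an exact O(L * u_max) candidate scan
# with explicit extension is practical and fully deterministic, unlike
# probabilistic repeat finders.

#' Find tandem repeats in a nucleotide region
#'
#' Exhaustive scan over unit lengths `min_unit..max_unit` and start
#' positions. The consensus is the first copy; each successive full
#' `u`-block must match the consensus at identity >= `min_identity`. A
#' fractional trailing copy is counted as (length of the exactly matching
#' consensus prefix)/u. Hits are canonicalized so that they begin at a
#' position whose first base agrees between copy 1 and copy 2 (leading
#' mismatches are trimmed), then overlapping hits are resolved by longer
#' total span, then higher identity, then smaller unit length; survivors are
#' reported sorted by start.
#'
#' @param region nucleotide string (a control region, typically).
#' @param min_unit minimum unit length, bp.
#' @param max_unit maximum unit length, bp.
#' @param min_copies minimum (fractional) copy number for a reportable hit.
#' @param min_identity minimum per-block identity to the consensus.
#' @return data frame with columns `start` (0-based position in the
#'   region), `unit_length`, `copies`, `identity`, `span_bp`, `consensus`,
#'   sorted by `start`. A region shorter than `2 * min_unit` yields an
#'   empty result with a warning.
#' @export
find_tandem_repeats <- function(region, min_unit = 5L, max_unit = 400L,
                                min_copies = 1.9, min_identity = 0.9) {
  empty <- data.frame(start = integer(0), unit_length = integer(0),
                      copies = numeric(0), identity = numeric(0),
                      span_bp = integer(0), consensus = character(0),
                      stringsAsFactors = FALSE)
  x <- .s2v(toupper(region))
  L <- length(x)
  if (L < 2L * min_unit) {
    warning("region shorter than 2 * min_unit; no repeats detectable")
    return(empty)
  }
  cand <- list()
  for (u in min_unit:min(max_unit, L %/% 2L)) {
    eq <- x[seq_len(L - u)] == x[seq_len(L - u) + u]
    cs <- c(0L, cumsum(eq))
    smax <- L - 2L * u                       # 0-based start candidates
    s_all <- 0:smax
    id2 <- (cs[s_all + u + 1L] - cs[s_all + 1L]) / u
    starts <- s_all[id2 >= min_identity]
    if (length(starts) == 0L) next
    seen <- integer(0)
    for (s in starts) {
      # canonical start: trim leading positions where copy1 and copy2
      # disagree at lag u
      while (s < smax && !eq[s + 1L]) s <- s + 1L
      if (s %in% seen) next
      hit <- .extend_repeat(x, s, u, min_identity)
      seen <- c(seen, s)
      if (is.null(hit) || hit$copies < min_copies) next
      cand[[length(cand) + 1L]] <- hit
    }
  }
  if (length(cand) == 0L) return(empty)
  df <- do.call(rbind, lapply(cand, as.data.frame, stringsAsFactors = FALSE))
  df <- df[!duplicated(df[c("start", "unit_length")]), , drop = FALSE]
  # overlap resolution: longer span, then higher identity, then smaller unit
  df <- df[order(-df$span_bp, -df$identity, df$unit_length, df$start), ,
           drop = FALSE]
  keep <- logical(nrow(df))
  iv <- matrix(0L, 0L, 2L)
  for (i in seq_len(nrow(df))) {
    a <- df$start[i]; b <- df$start[i] + df$span_bp[i]
    if (nrow(iv) == 0L || all(b <= iv[, 1L] | a >= iv[, 2L])) {
      keep[i] <- TRUE
      iv <- rbind(iv, c(a, b))
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df[c("start", "unit_length", "copies", "identity", "span_bp", "consensus")]
}

# Extend a candidate (s, u): full copies while block identity to the first
# copy stays >= min_identity, then an exactly matching consensus prefix as
# the fractional trailing copy.
#' @keywords internal
.extend_repeat <- function(x, s, u, min_identity) {
  L <- length(x)
  consensus <- x[(s + 1L):(s + u)]
  k <- 1L
  j <- s + u                                   # 0-based start of next block
  matched <- 0L                                # matches in copies 2..k
  while (j + u <= L) {
    m <- sum(x[(j + 1L):(j + u)] == consensus)
    if (m / u < min_identity) break
    k <- k + 1L
    matched <- matched + m
    j <- j + u
  }
  rem <- min(u - 1L, L - j)
  p <- 0L
  if (rem > 0L) {
    cmp <- x[(j + 1L):(j + rem)] == consensus[seq_len(rem)]
    p <- if (all(cmp)) rem else which(!cmp)[1L] - 1L
  }
  copies <- k + p / u
  if (k < 2L && p == 0L) return(NULL)
  denom <- (k - 1L) * u + p
  identity <- if (denom > 0L) (matched + p) / denom else 1
  list(start = s, unit_length = u, copies = copies, identity = identity,
       span_bp = k * u + p, consensus = .v2s(consensus))
}
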