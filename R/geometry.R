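# Gene overlap / intergenic spacer accounting from the feature table.
# Features (including the control region) are sorted by start with circular
# closure, one adjacency record per consecutive pair; strand is ignored.

#' Adjacency table of overlaps, spacers and abutments
#'
#' Sorts all features by start (then end), pairs each with its successor and
#' the last with the first across the circular origin, and classifies every
#' junction: `overlap` (next starts before previous ends), `spacer`
#' (intergenic gap) or `abutting` (0 bp). A feature nested inside another is
#' reported as an overlap of the inner feature's full length, with a
#' warning. The result is independent of the input feature order.
#'
#' @param genome a [mito_genome()].
#' @return data frame with columns `upstream`, `downstream`, `relation`,
#'   `length_bp`.
#' @export
adjacency_table <- function(genome) {
  ft <- genome$features
  if (nrow(ft) < 2L) stop("need at least two features")
  L <- genome_length(genome)
  ft <- ft[order(ft$start, ft$end), , drop = FALSE]
  n <- nrow(ft)
  up <- ft[seq_len(n), , drop = FALSE]
  dn <- ft[c(seq_len(n - 1L) + 1L, 1L), , drop = FALSE]
  dn_start <- dn$start
  dn_end <- dn$end
  if (genome$circular) {
    dn_start[n] <- dn_start[n] + L
    dn_end[n] <- dn_end[n] + L
  } else {
    up <- up[-n, , drop = FALSE]; dn <- dn[-n, , drop = FALSE]
    dn_start <- dn_start[-n]; dn_end <- dn_end[-n]
  }
  gap <- dn_start - up$end
  nested <- dn_end <= up$end
  if (any(nested)) {
    warning("nested feature(s): ",
            paste(dn$name[nested], collapse = ", "),
            " contained in ", paste(up$name[nested], collapse = ", "))
  }
  length_bp <- ifelse(nested, dn_end - dn_start, abs(gap))
  relation <- ifelse(gap < 0L, "overlap",
                     ifelse(gap > 0L, "spacer", "abutting"))
  out <- data.frame(upstream = up$name, downstream = dn$name,
                    relation = relation, length_bp = as.integer(length_bp),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summary of gene-overlap / spacer geometry
#'
#' @param records output of [adjacency_table()].
#' @return list with `n_overlaps`, `longest_overlap`,
#'   `longest_overlap_pair`, `n_spacers`, `total_spacer_bp`,
#'   `longest_spacer`, `longest_spacer_pair`. Ties are broken by first
#'   occurrence in genome order; empty categories report length `NA` and
#'   pair `NA`.
#' @export
geometry_summary <- function(records) {
  ov <- records[records$relation == "overlap", , drop = FALSE]
  sp <- records[records$relation == "spacer", , drop = FALSE]
  pick <- function(df) {
    if (nrow(df) == 0L) return(list(len = NA_integer_, pair = NA_character_))
    i <- which.max(df$length_bp)  # first occurrence wins ties
    list(len = df$length_bp[i],
         pair = paste(df$upstream[i], df$downstream[i], sep = "/"))
  }
  o <- pick(ov); s <- pick(sp)
  list(n_overlaps = nrow(ov), longest_overlap = o$len,
       longest_overlap_pair = o$pair,
       n_spacers = nrow(sp), total_spacer_bp = sum(sp$length_bp),
       longest_spacer = s$len, longest_spacer_pair = s$pair)
}
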