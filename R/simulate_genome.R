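# Synthetic annotated mitogenome generator with known ground truth.
# The genome follows the canonical 37-gene insect layout (13 PCGs, 22
# tRNAs, 2 rRNAs, control region; 14 genes on the minority strand), with
# controllable base composition, planted gene overlaps/spacers and planted
# control-region tandem repeats. Base pools use exact largest-remainder
# allocation so realized composition tracks the target to within rounding;
# PCGs get valid ATN starts, in-frame stop-free bodies and TAA/TAG or
# truncated stops.

.BASES <- c("A", "C", "G", "T")

# Canonical insect gene order with typical lengths (bp, on the genome) and
# default start/stop plan. Truncated stops imply length = 1 or 2 mod 3.
#' @keywords internal
.default_layout <- function(cr_length = 1776L) {
  d <- function(name, kind, strand, len, start = NA, stop = NA) {
    data.frame(name = name, kind = kind, strand = strand,
               length = as.integer(len), start_codon = start,
               stop_type = stop, stringsAsFactors = FALSE)
  }
  rbind(
    d("trnI", "tRNA", "J", 65), d("trnQ", "tRNA", "N", 68),
    d("trnM", "tRNA", "J", 68),
    d("nad2", "PCG", "J", 1023, "ATT", "TAA"),
    d("trnW", "tRNA", "J", 67), d("trnC", "tRNA", "N", 64),
    d("trnY", "tRNA", "N", 65),
    d("cox1", "PCG", "J", 1536, "ATG", "TAA"),
    d("trnL2", "tRNA", "J", 66),
    d("cox2", "PCG", "J", 688, "ATG", "T"),
    d("trnK", "tRNA", "J", 71), d("trnD", "tRNA", "J", 66),
    d("atp8", "PCG", "J", 162, "ATT", "TAA"),
    d("atp6", "PCG", "J", 678, "ATA", "TAA"),
    d("cox3", "PCG", "J", 789, "ATG", "TAA"),
    d("trnG", "tRNA", "J", 62),
    d("nad3", "PCG", "J", 354, "ATT", "TAA"),
    d("trnA", "tRNA", "J", 64), d("trnR", "tRNA", "J", 64),
    d("trnN", "tRNA", "J", 65), d("trnS1", "tRNA", "J", 66),
    d("trnE", "tRNA", "J", 65), d("trnF", "tRNA", "N", 62),
    d("nad5", "PCG", "N", 1720, "ATT", "T"),
    d("trnH", "tRNA", "N", 62),
    d("nad4", "PCG", "N", 1341, "ATA", "TAA"),
    d("nad4l", "PCG", "N", 288, "ATG", "TAA"),
    d("trnT", "tRNA", "J", 64), d("trnP", "tRNA", "N", 64),
    d("nad6", "PCG", "J", 522, "ATT", "TAA"),
    d("cob", "PCG", "J", 1137, "ATG", "TAA"),
    d("trnS2", "tRNA", "J", 67),
    d("nad1", "PCG", "N", 948, "ATA", "TAA"),
    d("trnL1", "tRNA", "N", 62), d("rrnL", "rRNA", "N", 1280),
    d("trnV", "tRNA", "N", 70), d("rrnS", "rRNA", "N", 770),
    d("CR", "control_region", "J", cr_length)
  )
}

# Default junction plan emulating a typical firefly mitogenome: 7 overlaps
# (1-4 bp, longest at atp8/atp6 and nad4/nad4l) and 13 spacers totalling
# 211 bp with the longest (72 bp) at the trnW/trnC junction. Negative =
# overlap, positive = spacer, 0 = abutting; names are "upstream|downstream".
#' @keywords internal
.default_junctions <- function() {
  c("atp8|atp6" = -4, "nad4|nad4l" = -4, "cox1|trnL2" = -1,
    "nad3|trnA" = -1, "trnE|trnF" = -1, "nad5|trnH" = -2, "cob|trnS2" = -1,
    "trnW|trnC" = 72, "trnI|trnQ" = 24, "trnQ|trnM" = 3, "trnY|cox1" = 2,
    "cox2|trnK" = 18, "trnK|trnD" = 1, "cox3|trnG" = 9, "trnA|trnR" = 16,
    "trnN|trnS1" = 5, "trnS1|trnE" = 21, "nad4l|trnT" = 10,
    "trnT|trnP" = 17, "trnP|nad6" = 13)
}

#' Specification for a synthetic mitogenome
#'
#' Defaults emulate a typical firefly mitogenome: A+T target 76.7% with the
#' composition split A 42.5 / C 13.9 / G 9.4 / T 34.2, seven gene overlaps
#' (longest 4 bp at atp8/atp6 and nad4/nad4l), thirteen intergenic spacers
#' totalling 211 bp (longest 72 bp), a 1776 bp control region carrying a
#' 136 bp unit repeated twice and a 171 bp unit repeated twice plus a 9 bp
#' partial third copy.
#'
#' @param composition named fractions for A, C, G, T (must sum to 1).
#' @param layout gene plan data frame (see `mitocomp:::.default_layout`).
#' @param junctions named vector of junction lengths, negative = overlap.
#' @param planted_repeats list of `c(unit_length, copies)` for the control
#'   region; `copies` may be fractional (partial trailing copy).
#' @param cr_length control-region length, bp.
#' @param seed RNG seed; identical spec + seed gives byte-identical output.
#' @return object of class `synthetic_genome_spec`.
#' @export
synthetic_genome_spec <- function(
    composition = c(A = 0.425, C = 0.139, G = 0.094, T = 0.342),
    layout = NULL,
    junctions = .default_junctions(),
    planted_repeats = list(c(136, 2), c(171, 2 + 9 / 171)),
    cr_length = 1776L,
    seed = 1L) {
  if (abs(sum(composition) - 1) > 1e-9) stop("composition must sum to 1")
  if (is.null(layout)) layout <- .default_layout(cr_length)
  stopifnot(all(names(composition) == .BASES))
  # feasibility checks
  jn <- strsplit(names(junctions), "|", fixed = TRUE)
  for (k in seq_along(junctions)) {
    up <- jn[[k]][1L]; dn <- jn[[k]][2L]
    if (!all(c(up, dn) %in% layout$name)) {
      stop("junction references unknown gene: ", names(junctions)[k])
    }
    ov <- -junctions[k]
    if (ov > 0) {
      lu <- layout$length[layout$name == up]
      ld <- layout$length[layout$name == dn]
      if (ov >= min(lu, ld)) stop("overlap exceeds gene length at ",
                                  names(junctions)[k])
      both_pcg <- all(layout$kind[layout$name %in% c(up, dn)] == "PCG")
      if (both_pcg && ov != 4) {
        stop("PCG-PCG overlaps are only supported at 4 bp (shared ATAA ",
             "start/stop motif); got ", ov, " at ", names(junctions)[k])
      }
    }
  }
  rep_span <- sum(vapply(planted_repeats, function(r) {
    u <- r[1L]; ceiling(r[2L] * u)
  }, numeric(1)))
  guard <- 80L * length(planted_repeats) + 120L
  if (rep_span + guard > cr_length) {
    stop("planted repeats (", rep_span, " bp + guards) exceed the control ",
         "region (", cr_length, " bp)")
  }
  structure(list(composition = composition, layout = layout,
                 junctions = junctions, planted_repeats = planted_repeats,
                 cr_length = as.integer(cr_length), seed = as.integer(seed)),
            class = "synthetic_genome_spec")
}

# exact-count random base vector with the target composition
#' @keywords internal
.bg_pool <- function(n, comp) {
  if (n == 0L) return(character(0))
  counts <- .allocate_counts(n, comp)
  sample(rep(.BASES, counts))
}

# Fixed-point adjustment: per-codon sampling probabilities over the 62
# non-stop codons whose average positional base marginal equals the target.
#' @keywords internal
.codon_probs <- function(comp) {
  gc5 <- genetic_code_5()
  sense <- names(gc5)[gc5 != "*"]
  cm <- do.call(rbind, strsplit(sense, "", fixed = TRUE))
  count_b <- vapply(.BASES, function(b) rowSums(cm == b), numeric(length(sense)))
  q <- comp
  for (it in 1:80) {
    w <- q[cm[, 1L]] * q[cm[, 2L]] * q[cm[, 3L]]
    p <- w / sum(w)
    marg <- colSums(p * count_b) / 3
    if (max(abs(marg - comp)) < 1e-12) break
    q <- q * comp / marg
    q <- q / sum(q)
  }
  stats::setNames(as.numeric(p), sense)
}

# Largest-remainder allocation over 62 codons leaves a small systematic
# base-marginal error; repair it by swapping single-base codon variants
# (decrement a codon carrying the over-represented base, increment the
# sense codon with that base replaced by the under-represented one).
#' @keywords internal
.repair_codon_counts <- function(counts, codons, comp, n_body) {
  cm <- do.call(rbind, strsplit(codons, "", fixed = TRUE))
  base_mat <- vapply(.BASES, function(b) rowSums(cm == b),
                     numeric(length(codons)))
  err <- colSums(counts * base_mat) - 3 * n_body * comp[.BASES]
  idx <- stats::setNames(seq_along(codons), codons)
  for (it in 1:400) {
    ov <- which.max(err); un <- which.min(err)
    if (err[ov] < 0.75 || err[un] > -0.75) break
    done <- FALSE
    cand <- which(counts > 0L & base_mat[, ov] > 0L)
    for (x in cand[order(-counts[cand])]) {
      pos <- which(cm[x, ] == .BASES[ov])
      for (q in pos) {
        v <- cm[x, ]
        v[q] <- .BASES[un]
        y <- idx[.v2s(v)]
        if (!is.na(y)) {
          counts[x] <- counts[x] - 1L
          counts[y] <- counts[y] + 1L
          err[ov] <- err[ov] - 1
          err[un] <- err[un] + 1
          done <- TRUE
          break
        }
      }
      if (done) break
    }
    if (!done) break
  }
  counts
}

# Build one PCG coding sequence: start codon + exact-count stop-free body +
# stop (TAA/TAG complete, or truncated T/TA). head_A forces the first body
# codon to begin with A; tail_A forces the last body codon to end with A
# (the shared-overlap motif).
#' @keywords internal
.build_pcg <- function(len, start_codon, stop_type, comp,
                       head_A = FALSE, tail_A = FALSE) {
  n_body <- (len - 3L - nchar(stop_type)) / 3L
  if (n_body != round(n_body) || n_body < 1L) {
    stop("PCG length ", len, " incompatible with stop '", stop_type, "'")
  }
  p <- .codon_probs(comp)
  counts <- .allocate_counts(n_body, p)
  counts <- .repair_codon_counts(counts, names(p), comp, n_body)
  codons <- sample(rep(names(p), counts))
  if (head_A) {
    i <- which(substr(codons, 1L, 1L) == "A")[1L]
    if (is.na(i)) codons[1L] <- "AAT"
    else codons[c(1L, i)] <- codons[c(i, 1L)]
  }
  if (tail_A) {
    n <- length(codons)
    i <- which(substr(codons, 3L, 3L) == "A" & seq_along(codons) != 1L)
    i <- i[length(i)]
    if (length(i) == 0L) codons[n] <- "TTA"
    else codons[c(n, i)] <- codons[c(i, n)]
  }
  paste0(start_codon, .v2s(codons), stop_type)
}

# Control region with planted tandem repeats. Flanking windows around each
# planted block are forced to mismatch the would-be consensus continuation
# so the planted hit is exactly maximal (unit length, copies and span are
# recoverable without off-by-one extension).
#' @keywords internal
.build_cr <- function(cr_length, comp, planted_repeats) {
  blocks <- lapply(planted_repeats, function(r) {
    u <- as.integer(r[1L])
    copies <- r[2L]
    k <- floor(copies + 1e-9)
    p <- as.integer(round((copies - k) * u))
    unit <- .bg_pool(u, comp)
    list(unit = unit, u = u, k = k, p = p,
         seqv = c(rep(unit, k), unit[seq_len(p)]))
  })
  total_block <- sum(vapply(blocks, function(b) length(b$seqv), integer(1)))
  n_bg <- cr_length - total_block
  bg <- .bg_pool(n_bg, comp)
  lead <- 100L
  gap <- 60L
  cr <- character(0)
  bg_i <- 0L
  take_bg <- function(n) {
    if (n == 0L) return(character(0))
    v <- bg[(bg_i + 1L):(bg_i + n)]
    bg_i <<- bg_i + n
    v
  }
  # composition-preserving guard edit: replace `old` by an allowed base and
  # give `old` back to an unplaced background position holding that base
  swap_guard <- function(old, forbidden) {
    allowed <- setdiff(.BASES, forbidden)
    pool <- which(bg[(bg_i + 1L):n_bg] %in% allowed)
    if (length(pool) == 0L) return(sample(allowed, 1L))
    j <- bg_i + pool[sample.int(length(pool), 1L)]
    new <- bg[j]
    bg[j] <<- old
    new
  }
  truth <- list()
  pos <- 0L
  cr <- c(cr, take_bg(lead)); pos <- pos + lead
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    gw <- min(floor(0.1 * b$u) + 2L, b$u)
    # pre-guard: last gw background bases must mismatch the unit tail
    pre_idx <- (length(cr) - gw + 1L):length(cr)
    need <- b$unit[(b$u - gw + 1L):b$u]
    for (t in seq_along(pre_idx)) {
      if (cr[pre_idx[t]] == need[t]) {
        cr[pre_idx[t]] <- swap_guard(cr[pre_idx[t]], need[t])
      }
    }
    truth[[bi]] <- data.frame(
      start = pos, unit_length = b$u, copies = b$k + b$p / b$u,
      span_bp = length(b$seqv), unit = .v2s(b$unit),
      stringsAsFactors = FALSE)
    cr <- c(cr, b$seqv); pos <- pos + length(b$seqv)
    # post-guard: next gw background bases must mismatch the consensus
    # continuation after the partial copy
    cont <- b$unit[((b$p + seq_len(gw) - 1L) %% b$u) + 1L]
    post <- take_bg(min(gap, n_bg - bg_i))
    for (t in seq_len(min(gw, length(post)))) {
      if (post[t] == cont[t]) {
        post[t] <- swap_guard(post[t], cont[t])
      }
    }
    cr <- c(cr, post); pos <- pos + length(post)
  }
  cr <- c(cr, take_bg(n_bg - bg_i))
  list(seq = cr, truth = do.call(rbind, truth))
}

#' Generate a synthetic annotated mitogenome with ground truth
#'
#' @param spec a [synthetic_genome_spec()].
#' @return list with `genome` (a [mito_genome()]) and `truth` (target
#'   composition, junction plan, planted repeat table with 0-based starts
#'   inside the control region, control-region coordinates, and the
#'   start/stop plan).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  set.seed(spec$seed)
  comp <- spec$composition
  comp_N <- comp[c("T", "G", "C", "A")]  # coding target for N-strand genes
  names(comp_N) <- .BASES
  lay <- spec$layout
  n <- nrow(lay)
  jn <- numeric(n)  # junction AFTER gene i (last = wrap)
  names(jn) <- paste(lay$name, lay$name[c(2:n, 1L)], sep = "|")
  unknown <- setdiff(names(spec$junctions), names(jn))
  if (length(unknown)) {
    stop("junction(s) not between consecutive genes: ",
         paste(unknown, collapse = ", "))
  }
  jn[names(spec$junctions)] <- spec$junctions
  if (jn[n] < 0) stop("overlap across the origin junction is not supported")

  # Motif constraints for 4 bp PCG-PCG overlaps: the shared genome bases are
  # one gene's <body A>TAA stop and the other's ATA<A> start ("ATAA", or its
  # reverse complement for an N/N pair). On the J strand the upstream gene
  # contributes its stop and the downstream its start; on the N strand the
  # roles flip because coding order is reversed. Mixed-strand PCG-PCG
  # overlaps have no compatible motif and are rejected.
  ovl_start_motif <- ovl_stop_motif <- character(0)
  for (k in which(jn < 0)) {
    pair <- strsplit(names(jn)[k], "|", fixed = TRUE)[[1L]]
    ki <- match(pair, lay$name)
    if (all(lay$kind[ki] == "PCG")) {
      strands <- lay$strand[ki]
      if (length(unique(strands)) != 1L) {
        stop("mixed-strand PCG-PCG overlap not supported at ", names(jn)[k])
      }
      if (strands[1L] == "J") {
        ovl_stop_motif <- c(ovl_stop_motif, pair[1L])
        ovl_start_motif <- c(ovl_start_motif, pair[2L])
      } else {
        ovl_start_motif <- c(ovl_start_motif, pair[1L])
        ovl_stop_motif <- c(ovl_stop_motif, pair[2L])
      }
    }
  }

  genome <- character(0)
  feats <- vector("list", n)
  cr_truth <- NULL
  cr_start <- NA_integer_
  for (i in seq_len(n)) {
    g <- lay[i, ]
    ctarget <- if (g$strand == "N") comp_N else comp
    if (g$kind == "PCG") {
      start_codon <- g$start_codon
      stop_type <- g$stop_type
      if (g$name %in% ovl_start_motif) start_codon <- "ATA"
      if (g$name %in% ovl_stop_motif) stop_type <- "TAA"
      coding <- .build_pcg(g$length, start_codon, stop_type, ctarget,
                           head_A = g$name %in% ovl_start_motif,
                           tail_A = g$name %in% ovl_stop_motif)
      seqv <- .s2v(if (g$strand == "J") coding else .revcomp(coding))
    } else if (g$kind == "control_region") {
      cr <- .build_cr(g$length, comp, spec$planted_repeats)
      seqv <- cr$seq
      cr_truth <- cr$truth
    } else {
      # unconstrained genes are laid down directly on the genome strand,
      # which is where the composition target applies
      seqv <- .bg_pool(g$length, comp)
    }
    ov <- if (i == 1L) 0L else max(0L, as.integer(-jn[i - 1L]))
    sp <- if (i == 1L) 0L else max(0L, as.integer(jn[i - 1L]))
    if (sp > 0L) genome <- c(genome, .bg_pool(sp, comp))
    if (ov > 0L) {
      tail_seq <- genome[(length(genome) - ov + 1L):length(genome)]
      if (g$kind == "PCG") {
        if (!identical(seqv[seq_len(ov)], tail_seq)) {
          stop("internal error: overlap motif mismatch at ", g$name)
        }
      } else {
        seqv[seq_len(ov)] <- tail_seq  # unconstrained gene absorbs overlap
      }
    }
    start <- length(genome) - ov
    genome <- c(genome, seqv[(ov + 1L):length(seqv)])
    if (g$kind == "control_region") cr_start <- start
    feats[[i]] <- data.frame(
      name = g$name, kind = g$kind, start = start, end = start + g$length,
      strand = g$strand,
      codon_start = if (g$kind == "PCG") 0L else NA_integer_,
      stringsAsFactors = FALSE)
  }
  features <- do.call(rbind, feats)
  gnm <- mito_genome(sprintf("SYNTH%06d", spec$seed), .v2s(genome),
                     circular = TRUE, features = features)
  truth <- list(composition = comp, junctions = jn,
                repeats = cr_truth, cr_start = cr_start,
                layout = lay, genome_length = genome_length(gnm))
  list(genome = gnm, truth = truth)
}
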