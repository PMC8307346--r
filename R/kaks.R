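# Nei-Gojobori (1986) Ka/Ks under the invertebrate mitochondrial code:
# synonymous site fractions from single-base mutational neighborhoods with
# mutations to stop codons excluded from the denominator; multi-hit codons
# averaged over all minimal mutational pathways, discarding pathways through
# stop codons; Jukes-Cantor correction of the proportions.

.kaks_env <- new.env(parent = emptyenv())

# per-codon synonymous site count: sum over the 3 positions of
# (synonymous non-stop changes) / (non-stop changes); positions where every
# change creates a stop contribute 0 synonymous sites (and a full
# non-synonymous site).
#' @keywords internal
.syn_sites <- function() {
  if (!is.null(.kaks_env$syn_sites)) return(.kaks_env$syn_sites)
  gc5 <- genetic_code_5()
  sense <- names(gc5)[gc5 != "*"]
  bases <- c("A", "C", "G", "T")
  s <- stats::setNames(numeric(length(sense)), sense)
  for (cod in sense) {
    v <- .s2v(cod)
    tot <- 0
    for (pos in 1:3) {
      syn <- 0L; nonstop <- 0L
      for (b in setdiff(bases, v[pos])) {
        w <- v; w[pos] <- b
        aa <- gc5[[.v2s(w)]]
        if (aa == "*") next
        nonstop <- nonstop + 1L
        if (aa == gc5[[cod]]) syn <- syn + 1L
      }
      if (nonstop > 0L) tot <- tot + syn / nonstop
    }
    s[cod] <- tot
  }
  .kaks_env$syn_sites <- s
  s
}

# Pathway-averaged (Sd, Nd) for one codon pair, memoized. Enumerates the
# k! orders of the k differing positions, drops orders passing through a
# stop codon (falling back to all orders if every one does), classifies each
# single-base step as synonymous or not, and averages.
#' @keywords internal
.codon_pair_diffs <- function(codA, codB) {
  key <- paste0(codA, codB)
  if (is.null(.kaks_env$pair_cache)) {
    .kaks_env$pair_cache <- new.env(parent = emptyenv())
  }
  hit <- get0(key, envir = .kaks_env$pair_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  gc5 <- genetic_code_5()
  a <- .s2v(codA); b <- .s2v(codB)
  pos <- which(a != b)
  k <- length(pos)
  res <- if (k == 0L) {
    c(Sd = 0, Nd = 0)
  } else {
    orders <- switch(k,
                     list(pos),
                     list(pos, pos[2:1]),
                     list(pos[c(1, 2, 3)], pos[c(1, 3, 2)], pos[c(2, 1, 3)],
                          pos[c(2, 3, 1)], pos[c(3, 1, 2)], pos[c(3, 2, 1)]))
    eval_path <- function(ord) {
      cur <- a
      sd <- 0; nd <- 0; through_stop <- FALSE
      for (p in ord) {
        nxt <- cur
        nxt[p] <- b[p]
        aa1 <- gc5[[.v2s(cur)]]; aa2 <- gc5[[.v2s(nxt)]]
        if (aa2 == "*" && !identical(nxt, b)) through_stop <- TRUE
        if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      list(sd = sd, nd = nd, valid = !through_stop)
    }
    paths <- lapply(orders, eval_path)
    valid <- vapply(paths, `[[`, logical(1), "valid")
    if (!any(valid)) valid <- rep(TRUE, length(paths))  # fallback: all paths
    sd <- mean(vapply(paths[valid], `[[`, numeric(1), "sd"))
    nd <- mean(vapply(paths[valid], `[[`, numeric(1), "nd"))
    c(Sd = sd, Nd = nd)
  }
  assign(key, res, envir = .kaks_env$pair_cache)
  res
}

#' Jukes-Cantor corrected proportion
#' @param p proportion of differences per site.
#' @return -3/4 ln(1 - 4p/3); `NA` (saturated) for p >= 0.75.
#' @export
jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Nei-Gojobori (1986) Ka/Ks for one pair of coding sequences
#'
#' Codon pairs containing a gap or ambiguity in either sequence are deleted
#' (codon-wise pairwise deletion). Synonymous (S) and non-synonymous (N)
#' site counts are averaged over the two sequences; S + N = 3 x codons.
#' Differences at multi-hit codons are averaged over all minimal mutational
#' pathways, discarding pathways through stop codons. ps = Sd/S and pn =
#' Nd/N get the Jukes-Cantor correction.
#'
#' @param seqA,seqB equal-length, in-frame coding sequences (length a
#'   multiple of 3).
#' @return object of class `kaks_record`: list with `Sd`, `Nd`, `S`, `N`,
#'   `ps`, `pn`, `Ks`, `Ka`, `omega`, `n_codons`, `saturated`. `omega` is
#'   `NA` when Ks is 0 or saturated.
#' @export
ng86_kaks <- function(seqA, seqB) {
  a <- toupper(seqA); b <- toupper(seqB)
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  if (nchar(a) %% 3L != 0L) stop("length is not a multiple of 3")
  ca <- codon_split(a)$codons
  cb <- codon_split(b)$codons
  clean <- function(cv) {
    v <- strsplit(cv, "", fixed = TRUE)
    vapply(v, function(z) all(.is_acgt(z)), logical(1))
  }
  gc5 <- genetic_code_5()
  use <- clean(ca) & clean(cb) & gc5[ca] != "*" & gc5[cb] != "*"
  ca <- ca[use]; cb <- cb[use]
  ncod <- length(ca)
  if (ncod == 0L) stop("no usable codons after pairwise deletion")
  ss <- .syn_sites()
  S <- (sum(ss[ca]) + sum(ss[cb])) / 2
  N <- 3 * ncod - S
  Sd <- 0; Nd <- 0
  for (i in which(ca != cb)) {
    d <- .codon_pair_diffs(ca[i], cb[i])
    Sd <- Sd + d[["Sd"]]
    Nd <- Nd + d[["Nd"]]
  }
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  Ks <- if (is.na(ps)) NA_real_ else jc_correct(ps)
  Ka <- if (is.na(pn)) NA_real_ else jc_correct(pn)
  omega <- if (is.na(Ka) || is.na(Ks) || Ks == 0) NA_real_ else Ka / Ks
  structure(list(Sd = Sd, Nd = Nd, S = S, N = N, ps = ps, pn = pn,
                 Ks = Ks, Ka = Ka, omega = omega, n_codons = ncod,
                 saturated = (!is.na(ps) && ps >= 0.75) ||
                   (!is.na(pn) && pn >= 0.75)),
            class = "kaks_record")
}

#' Brute-force pathway-enumeration oracle for NG86 difference counts
#'
#' Reference implementation used for validation: enumerates every complete
#' minimal mutational path between two codons by depth-first recursion on
#' the codon graph (no caching, no precomputed tables), discards paths
#' through stop codons (all paths retained if none survive), and averages
#' the synonymous/non-synonymous step counts. Deliberately independent of
#' the optimized path used by [ng86_kaks()].
#'
#' @param codA,codB DNA codons (no gaps/ambiguities).
#' @return numeric vector `c(Sd, Nd)`.
#' @export
ng86_count_oracle <- function(codA, codB) {
  gc5 <- Biostrings::getGeneticCode("5")
  collect <- function(cur, target, sd, nd, stopped) {
    if (identical(cur, target)) {
      return(list(list(sd = sd, nd = nd, stopped = stopped)))
    }
    out <- list()
    for (p in which(cur != target)) {
      nxt <- cur
      nxt[p] <- target[p]
      same <- gc5[[paste0(cur, collapse = "")]] ==
        gc5[[paste0(nxt, collapse = "")]]
      hit_stop <- gc5[[paste0(nxt, collapse = "")]] == "*" &&
        !identical(nxt, target)
      out <- c(out, collect(nxt, target,
                            sd + as.numeric(same), nd + as.numeric(!same),
                            stopped || hit_stop))
    }
    out
  }
  a <- strsplit(codA, "", fixed = TRUE)[[1L]]
  b <- strsplit(codB, "", fixed = TRUE)[[1L]]
  if (identical(a, b)) return(c(Sd = 0, Nd = 0))
  paths <- collect(a, b, 0, 0, FALSE)
  ok <- !vapply(paths, `[[`, logical(1), "stopped")
  if (!any(ok)) ok <- rep(TRUE, length(paths))
  c(Sd = mean(vapply(paths[ok], `[[`, numeric(1), "sd")),
    Nd = mean(vapply(paths[ok], `[[`, numeric(1), "nd")))
}

#' Mean pairwise Ka/Ks over an alignment
#'
#' [ng86_kaks()] for every unordered taxon pair; the mean is taken over the
#' defined pairwise omega values (saturated or undefined pairs are excluded
#' and counted).
#'
#' @param aln in-frame codon [mito_alignment()].
#' @return list with `mean_omega`, `mean_ka`, `mean_ks`, `n_pairs`
#'   (defined), `n_undefined`, and the per-pair records in `pairs`.
#'   All pairs undefined is an error.
#' @export
gene_mean_kaks <- function(aln) {
  n <- length(aln$taxa)
  recs <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      recs[[length(recs) + 1L]] <- ng86_kaks(aln$rows[i], aln$rows[j])
    }
  }
  om <- vapply(recs, `[[`, numeric(1), "omega")
  ka <- vapply(recs, `[[`, numeric(1), "Ka")
  ks <- vapply(recs, `[[`, numeric(1), "Ks")
  def <- !is.na(om)
  if (!any(def)) stop("no defined pairwise omega values")
  list(mean_omega = mean(om[def]),
       mean_ka = mean(ka[!is.na(ka)]),
       mean_ks = mean(ks[!is.na(ks)]),
       n_pairs = sum(def), n_undefined = sum(!def), pairs = recs)
}
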