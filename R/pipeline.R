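# Orchestration of the two workflows: single-genome characterization
# (composition/skew table, start/stop codons, overlap/spacer geometry,
# control-region repeats) and multi-genome comparison (per-gene Pi, mean
# K2P, mean Ka/Ks, sliding-window profile, Bowker heterogeneity matrices).
# All tables are deterministic given inputs; re-running writes byte-identical
# TSVs.

#' Single-genome characterization bundle
#'
#' Runs [region_composition()], [start_stop_table()], [adjacency_table()] /
#' [geometry_summary()] and [find_tandem_repeats()] on the control region.
#' A genome lacking a control-region annotation gets an empty repeat table
#' with a warning.
#'
#' @param genome a [mito_genome()].
#' @param out_dir optional directory; when given, each table is written as
#'   TSV plus a `run_info.json` log and a `data_dictionary.tsv`.
#' @param repeat_args list of arguments passed on to [find_tandem_repeats()].
#' @return list with `composition`, `start_stop`, `adjacency`, `geometry`,
#'   `repeats`.
#' @export
characterize <- function(genome, out_dir = NULL, repeat_args = list()) {
  comp <- region_composition(genome)
  ss <- start_stop_table(genome)
  adj <- adjacency_table(genome)
  geo <- geometry_summary(adj)
  cr_idx <- which(genome$features$kind == "control_region")
  reps <- if (length(cr_idx)) {
    cr_seq <- extract_gene_sequence(genome, cr_idx[1L])
    do.call(find_tandem_repeats, c(list(region = cr_seq), repeat_args))
  } else {
    warning("no control-region annotation; repeat table empty")
    find_tandem_repeats(strrep("A", 0L), min_unit = 1L)
  }
  out <- list(composition = comp, start_stop = ss, adjacency = adj,
              geometry = geo, repeats = reps)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(format_composition(comp),
                file.path(out_dir, "composition.tsv"))
    write_table(ss, file.path(out_dir, "start_stop.tsv"))
    write_table(adj, file.path(out_dir, "adjacency.tsv"))
    write_table(reps, file.path(out_dir, "repeats.tsv"))
    jsonlite::write_json(
      list(tool = "mitocomp",
           version = as.character(utils::packageVersion("mitocomp")),
           accession = genome$accession, geometry = geo,
           repeat_args = repeat_args),
      file.path(out_dir, "run_info.json"), auto_unbox = TRUE, digits = NA)
    .write_data_dictionary(out_dir)
  }
  out
}

#' Multi-genome comparative bundle
#'
#' Per-gene nucleotide diversity, mean pairwise K2P distance and mean
#' pairwise NG86 Ka/Ks; a sliding-window Pi profile on the concatenation of
#' the protein-coding alignments; Bowker pairwise symmetry matrices for the
#' all-positions dataset and the 1st+2nd-codon-position dataset (plus any
#' extra alignments, e.g. rRNA, appended to both).
#'
#' @param alignments named list of in-frame codon [mito_alignment()]s over
#'   the same taxa (one per protein-coding gene). Genes with fewer than 2
#'   taxa are skipped with a warning.
#' @param extra optional named list of non-coding alignments appended to the
#'   Bowker datasets.
#' @param window,step sliding-window parameters (bp).
#' @param out_dir optional output directory for TSV export.
#' @return list with `per_gene` (data frame), `window_profile` (data
#'   frame), `bowker` (list of [pairwise_symmetry()] results keyed by
#'   dataset name).
#' @export
compare_genomes <- function(alignments, extra = NULL,
                            window = 200L, step = 20L, out_dir = NULL) {
  keep <- vapply(alignments, function(a) length(a$taxa) >= 2L, logical(1))
  if (any(!keep)) {
    warning("skipping gene(s) with < 2 taxa: ",
            paste(names(alignments)[!keep], collapse = ", "))
    alignments <- alignments[keep]
  }
  if (length(alignments) == 0L) stop("no usable alignments")
  per_gene <- do.call(rbind, lapply(names(alignments), function(g) {
    a <- alignments[[g]]
    kk <- gene_mean_kaks(a)
    mk <- gene_mean_k2p(a)
    data.frame(gene = g, n_taxa = length(a$taxa), sites = aln_width(a),
               pi = suppressWarnings(nucleotide_diversity(a)),
               mean_k2p = as.numeric(mk),
               k2p_undefined = attr(mk, "n_undefined"),
               mean_ka = kk$mean_ka, mean_ks = kk$mean_ks,
               mean_omega = kk$mean_omega,
               omega_undefined = kk$n_undefined,
               stringsAsFactors = FALSE)
  }))
  concat <- aln_concat(alignments, gene = "PCG_concat")
  profile <- sliding_window_pi(concat, window = window, step = step)
  pos12 <- aln_subset(concat, which(seq_len(aln_width(concat)) %% 3L != 0L))
  ds_all <- if (is.null(extra)) concat else
    aln_concat(c(list(concat), unname(extra)), gene = "all")
  ds_12 <- if (is.null(extra)) pos12 else
    aln_concat(c(list(pos12), unname(extra)), gene = "pos12")
  bw <- list(all_positions = pairwise_symmetry(ds_all),
             positions_12 = pairwise_symmetry(ds_12))
  out <- list(per_gene = per_gene, window_profile = profile, bowker = bw)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(per_gene, file.path(out_dir, "per_gene_stats.tsv"))
    write_table(profile, file.path(out_dir, "window_profile.tsv"))
    for (nm in names(bw)) {
      write_table(symmetry_table(bw[[nm]]),
                  file.path(out_dir, paste0("bowker_", nm, ".tsv")))
    }
    .write_data_dictionary(out_dir)
  }
  out
}

#' Read a pipeline run configuration (JSON or YAML)
#'
#' @param path path to a `.json` or `.yaml`/`.yml` config file with fields
#'   such as `genbank`, `alignment_dir`, `window`, `step`, `repeat_args`,
#'   `out_dir`, `seed`.
#' @return named list of settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("yaml package required for YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  for (f in c("genbank", "alignment_dir")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop("config path does not exist: ", f, " = ", cfg[[f]])
    }
  }
  cfg
}

#' @keywords internal
.write_data_dictionary <- function(out_dir) {
  dd <- data.frame(
    column = c("region", "size_bp", "pctA/pctC/pctG/pctT", "pctAT/pctGC",
               "at_skew", "gc_skew", "gene", "start_codon", "stop_codon",
               "upstream/downstream", "relation", "length_bp", "start",
               "unit_length", "copies", "identity", "span_bp", "consensus",
               "n_taxa", "sites", "pi", "mean_k2p", "mean_ka", "mean_ks",
               "mean_omega", "midpoint", "taxonA/taxonB", "chi2", "p",
               "pass"),
    description = c(
      "genome partition label",
      "partition length in bp",
      "base percentage of A+C+G+T total (ambiguities excluded)",
      "combined A+T / G+C percentage",
      "(A - T) / (A + T) strand skew",
      "(G - C) / (G + C) strand skew",
      "canonical gene name",
      "first codon of the CDS; ATN expected",
      "terminal codon; T/TA marked (truncated)",
      "flanking genes of a junction, genome order",
      "overlap, spacer or abutting",
      "junction length in bp (0 iff abutting)",
      "0-based start position",
      "tandem repeat unit length in bp",
      "fractional copy number (partial trailing copy = prefix/unit)",
      "fraction of matching positions vs the first-copy consensus",
      "total repeat span in bp",
      "repeat unit consensus (first copy)",
      "number of sequences compared",
      "alignment columns",
      "nucleotide diversity (mean pairwise differences per usable site)",
      "mean pairwise Kimura 2-parameter distance",
      "mean pairwise NG86 Ka (Jukes-Cantor corrected)",
      "mean pairwise NG86 Ks (Jukes-Cantor corrected)",
      "mean pairwise Ka/Ks over defined pairs",
      "window start + window/2, alignment coordinates",
      "taxon pair of the Bowker test",
      "Bowker matched-pairs symmetry statistic",
      "upper-tail chi-square p-value",
      "TRUE iff p > 0.05 (no detected violation of symmetry)"),
    stringsAsFactors = FALSE
  )
  write_table(dd, file.path(out_dir, "data_dictionary.tsv"))
}
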