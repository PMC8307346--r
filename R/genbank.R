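# GenBank flat-file reader/writer. Converts GenBank 1-based inclusive
# coordinates to the internal 0-based half-open convention at the boundary;
# complement(...) locations map to strand "N"; join(a..L,1..b) across the
# origin maps to a single wrapped interval with end > genome length.

.kind_from_key <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                    `D-loop` = "control_region",
                    misc_feature = "control_region")

#' Read a GenBank flat file into a `mito_genome`
#'
#' Parses LOCUS, ACCESSION, the feature table (CDS/tRNA/rRNA/D-loop/
#' misc_feature keys) and the ORIGIN sequence. Gene labels are taken from
#' `/gene`, falling back to `/product`, and normalized with
#' [normalize_gene_name()]; a label that cannot be resolved raises a warning
#' and the feature kind is inferred from the feature key alone.
#'
#' @param path path to a GenBank flat file.
#' @return a [mito_genome()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^LOCUS", lines[1L])) {
    stop("malformed GenBank record at line 1: missing LOCUS line in ", path)
  }
  locus <- lines[1L]
  m <- regmatches(locus, regexec("^LOCUS\\s+(\\S+)\\s+(\\d+)\\s+bp", locus))[[1L]]
  if (length(m) < 3L) stop("malformed GenBank record at line 1: ", locus)
  name <- m[2L]
  declared_len <- as.integer(m[3L])
  circular <- grepl("circular", locus, ignore.case = TRUE)

  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  accession <- if (length(acc_line)) sub("^ACCESSION\\s+", "", acc_line[1L]) else name

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (length(fstart) == 0L) {
    stop("malformed GenBank record: no FEATURES section (line ",
         length(lines), " reached)")
  }
  if (length(ostart) == 0L) {
    stop("malformed GenBank record: no ORIGIN section")
  }
  fstart <- fstart[1L]; ostart <- ostart[1L]

  seq_lines <- lines[(ostart + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste0(seq_lines, collapse = "")))
  if (nchar(sequence) != declared_len) {
    warning("LOCUS declares ", declared_len, " bp but ORIGIN has ",
            nchar(sequence), " bp")
  }
  L <- nchar(sequence)

  feat_lines <- lines[(fstart + 1L):(ostart - 1L)]
  is_key <- grepl("^ {5}\\S", feat_lines)
  recs <- list()
  i <- 1L
  while (i <= length(feat_lines)) {
    if (!is_key[i]) { i <- i + 1L; next }
    key <- sub("^ {5}(\\S+).*$", "\\1", feat_lines[i])
    loc <- sub("^ {5}\\S+\\s+", "", feat_lines[i])
    quals <- character(0)
    j <- i + 1L
    # location continuation lines (no leading '/')
    while (j <= length(feat_lines) && !is_key[j] &&
           !grepl("^\\s+/", feat_lines[j])) {
      loc <- paste0(loc, trimws(feat_lines[j]))
      j <- j + 1L
    }
    while (j <= length(feat_lines) && !is_key[j]) {
      quals <- c(quals, trimws(feat_lines[j]))
      j <- j + 1L
    }
    if (key %in% names(.kind_from_key)) {
      recs[[length(recs) + 1L]] <- list(key = key, loc = loc, quals = quals,
                                        line = fstart + i)
    }
    i <- j
  }

  qual_value <- function(quals, what) {
    hit <- grep(paste0("^/", what, "="), quals, value = TRUE)
    if (length(hit) == 0L) return(NA_character_)
    gsub('^/[a-z_]+="?|"$', "", hit[1L])
  }

  rows <- lapply(recs, function(r) {
    p <- .parse_location(r$loc, L)
    if (is.null(p)) {
      stop("malformed GenBank record at line ", r$line,
           ": cannot parse location '", r$loc, "'")
    }
    label <- qual_value(r$quals, "gene")
    if (is.na(label)) label <- qual_value(r$quals, "product")
    kind <- .kind_from_key[[r$key]]
    name <- if (is.na(label)) NA_character_ else normalize_gene_name(label)
    if (is.na(name)) {
      if (kind == "control_region" && r$key == "misc_feature" &&
          !is.na(label) && !grepl("control|A\\+?T", label, ignore.case = TRUE)) {
        return(NULL)  # unrelated misc_feature
      }
      warning("unresolvable gene name '",
              if (is.na(label)) r$key else label,
              "'; kind inferred from feature key ", r$key)
      name <- if (kind == "control_region") "CR" else
        paste0(r$key, "_", p$start)
    }
    cs <- qual_value(r$quals, "codon_start")
    phase <- if (kind == "PCG") {
      if (is.na(cs)) 0L else as.integer(cs) - 1L
    } else NA_integer_
    data.frame(name = name, kind = kind, start = p$start, end = p$end,
               strand = p$strand, codon_start = phase,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no recognizable features in ", path)
  features <- do.call(rbind, rows)
  # de-duplicate gene + CDS double annotation: keep first occurrence
  features <- features[!duplicated(features[c("name", "start")]), ,
                       drop = FALSE]
  rownames(features) <- NULL
  mito_genome(accession, sequence, circular, features)
}

# Parse a GenBank location string. Returns list(start, end, strand) in
# internal coordinates, or NULL on failure.
#' @keywords internal
.parse_location <- function(loc, L) {
  loc <- gsub("\\s", "", loc)
  strand <- "J"
  if (grepl("^complement\\(", loc)) {
    strand <- "N"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  segs <- if (grepl("^join\\(", loc)) {
    strsplit(sub("^join\\((.*)\\)$", "\\1", loc), ",", fixed = TRUE)[[1L]]
  } else loc
  parse_seg <- function(s) {
    s <- gsub("[<>]", "", s)
    m <- regmatches(s, regexec("^(\\d+)\\.\\.(\\d+)$", s))[[1L]]
    if (length(m) == 3L) return(as.integer(m[2:3]))
    if (grepl("^\\d+$", s)) return(rep(as.integer(s), 2L))
    NULL
  }
  parsed <- lapply(segs, parse_seg)
  if (any(vapply(parsed, is.null, logical(1)))) return(NULL)
  if (length(parsed) == 1L) {
    a <- parsed[[1L]]
    if (a[1L] > a[2L]) return(NULL)
    return(list(start = a[1L] - 1L, end = a[2L], strand = strand))
  }
  if (length(parsed) == 2L && parsed[[1L]][2L] == L && parsed[[2L]][1L] == 1L) {
    # join across the circular origin -> wrapped interval
    return(list(start = parsed[[1L]][1L] - 1L, end = L + parsed[[2L]][2L],
                strand = strand))
  }
  NULL
}

#' Write a `mito_genome` as a GenBank flat file
#'
#' Emits LOCUS/ACCESSION, a feature table (CDS/tRNA/rRNA/D-loop keys with
#' `/gene` and `/codon_start` qualifiers) and the ORIGIN sequence block.
#' Coordinates are converted back to GenBank 1-based inclusive form; wrapped
#' features become `join(a..L,1..b)` and N-strand features
#' `complement(...)`. A genome written and re-read round-trips to the same
#' feature table.
#'
#' @param genome a [mito_genome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  L <- genome_length(genome)
  con <- file(path, "w")
  on.exit(close(con))
  topo <- if (genome$circular) "circular" else "linear"
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   INV",
                     genome$accession, L, topo), con)
  writeLines(sprintf("ACCESSION   %s", genome$accession), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  key_of <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
              control_region = "D-loop")
  ft <- genome$features
  for (i in seq_len(nrow(ft))) {
    loc <- if (ft$end[i] <= L) {
      sprintf("%d..%d", ft$start[i] + 1L, ft$end[i])
    } else {
      sprintf("join(%d..%d,1..%d)", ft$start[i] + 1L, L, ft$end[i] - L)
    }
    if (ft$strand[i] == "N") loc <- sprintf("complement(%s)", loc)
    key <- key_of[[ft$kind[i]]]
    writeLines(sprintf("     %-15s %s", key, loc), con)
    writeLines(sprintf('                     /gene="%s"', ft$name[i]), con)
    if (ft$kind[i] == "PCG" && !is.na(ft$codon_start[i])) {
      writeLines(sprintf("                     /codon_start=%d",
                         ft$codon_start[i] + 1L), con)
    }
  }
  writeLines("ORIGIN", con)
  v <- tolower(genome$sequence)
  pos <- seq(1L, L, by = 60L)
  for (p in pos) {
    chunk <- substr(v, p, min(p + 59L, L))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}
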