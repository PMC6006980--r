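# Sequence and report input/output. All coordinates are held 0-based
# half-open internally; conversion to 1-based inclusive happens only at
# format boundaries (GFF3).

AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

#' Create a protein record
#'
#' A protein record holds an identifier, an uppercase amino-acid sequence
#' (20-letter alphabet plus `X`) and an optional source label (e.g. the
#' ORF or cluster the protein came from).
#'
#' @param id Character identifier, unique within one input set.
#' @param sequence Amino-acid string; lowercase input is uppercased.
#' @param source Optional ORF/cluster label.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, source = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("protein_record: empty sequence for '", id, "'")
  bad <- regexpr(sprintf("[^%sX]", paste(AA_ALPHABET, collapse = "")), sequence)
  if (bad > 0L) {
    stop(sprintf("illegal residue '%s' in record '%s' at position %d",
                 substr(sequence, bad, bad), id, as.integer(bad)))
  }
  structure(list(id = id, sequence = sequence, source = source),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa)%s\n", x$id, nchar(x$sequence),
              if (is.na(x$source)) "" else paste0(" [", x$source, "]")))
  invisible(x)
}

#' @export
as.character.protein_record <- function(x, ...) x$sequence

#' Read protein sequences from a FASTA file
#'
#' Wrapped and unwrapped entries are both accepted; lowercase residues are
#' uppercased. Identifiers are taken from the header up to the first
#' whitespace.
#'
#' @param path Path to a protein FASTA file.
#' @return List of [protein_record] objects, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("read_fasta: file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("read_fasta: no records in ", path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) {
    stop("read_fasta: duplicate record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  mapply(function(i, s) protein_record(i, s), ids, as.character(aa),
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write protein records to FASTA
#'
#' @param records List of [protein_record] objects.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "protein_record")) records <- list(records)
  seqs <- vapply(records, function(r) r$sequence, character(1))
  aa <- Biostrings::AAStringSet(seqs)
  names(aa) <- vapply(records, function(r) r$id, character(1))
  Biostrings::writeXStringSet(aa, path, width = width)
  invisible(path)
}

#' Read translated CDS features from a GenBank flat file
#'
#' Extracts one protein record per CDS feature carrying a `/translation`
#' qualifier. A CDS without a translation is skipped with a warning.
#' Identifiers come from `/locus_tag`, `/gene` or `/protein_id`, in that
#' order of preference, falling back to `CDS_<n>`.
#'
#' @param path Path to a GenBank flat file.
#' @return List of [protein_record] objects.
#' @export
read_genbank_cds <- function(path) {
  if (!file.exists(path)) stop("read_genbank_cds: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(grepl("^LOCUS", lines)))
    stop("read_genbank_cds: not a GenBank flat file (no LOCUS line): ", path)
  feat_start <- grep("^FEATURES", lines)
  if (!length(feat_start))
    stop(sprintf("read_genbank_cds: malformed record, no FEATURES table (%s, line 1)",
                 path))
  end_mark <- grep("^(ORIGIN|//)", lines)
  feat_end <- if (length(end_mark)) min(end_mark[end_mark > feat_start[1]]) - 1L
              else length(lines)
  feat <- lines[(feat_start[1] + 1L):feat_end]

  # a feature key sits at column 6; qualifiers/continuations are indented past it
  key_idx <- grep("^ {5}\\S", feat)
  cds_idx <- key_idx[grepl("^ {5}CDS\\b", feat[key_idx])]
  recs <- list(); n_cds <- 0L
  for (k in cds_idx) {
    n_cds <- n_cds + 1L
    nxt <- key_idx[key_idx > k]
    block <- feat[k:(if (length(nxt)) min(nxt) - 1L else length(feat))]
    qual_text <- paste(sub("^\\s+", "", block[-1L]), collapse = "\n")
    get_q <- function(name) {
      m <- regmatches(qual_text,
                      regexec(sprintf('/%s="([^"]*)"', name), qual_text))[[1]]
      if (length(m) == 2L) m[2] else NA_character_
    }
    id <- get_q("locus_tag")
    if (is.na(id)) id <- get_q("gene")
    if (is.na(id)) id <- get_q("protein_id")
    if (is.na(id)) id <- sprintf("CDS_%d", n_cds)
    tr <- get_q("translation")
    if (is.na(tr)) {
      warning("read_genbank_cds: CDS '", id, "' has no /translation; skipped")
      next
    }
    tr <- gsub("[\n ]", "", tr)
    recs[[length(recs) + 1L]] <- protein_record(id, tr, source = basename(path))
  }
  recs
}

#' Write a domain-hit report
#'
#' Serializes a table of domain hits as TSV, JSON or GFF3. Hits are stored
#' 0-based half-open internally; GFF3 output is converted to the 1-based
#' inclusive convention of the GFF3 standard, while TSV/JSON keep the
#' internal convention and say so in a header comment / field.
#'
#' @param hits Data frame of domain hits (see [detect_domains()]).
#' @param path Output path.
#' @param format One of `"tsv"`, `"json"`, `"gff3"`.
#' @param config Optional named list echoed into the report header for
#'   reproducibility.
#' @return `path`, invisibly.
#' @export
write_report <- function(hits, path, format = c("tsv", "json", "gff3"),
                         config = NULL) {
  if (!is.character(format) || !all(format %in% c("tsv", "json", "gff3")))
    stop("write_report: unknown format '", format[1],
         "'; supported: tsv, json, gff3")
  format <- match.arg(format)
  hits <- as.data.frame(hits)
  cfg_lines <- if (length(config))
    sprintf("# config: %s", jsonlite::toJSON(config, auto_unbox = TRUE))
  if (format == "tsv") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("# coordinates: 0-based half-open", cfg_lines), con)
    if (nrow(hits)) {
      suppressWarnings(write.table(hits, con, sep = "\t", quote = FALSE,
                                   row.names = FALSE, col.names = TRUE))
    } else {
      writeLines(paste(c("protein_id", "domain_type", "start", "end",
                         "score", "active", "reason"), collapse = "\t"), con)
    }
  } else if (format == "json") {
    out <- list(coordinates = "0-based half-open", hits = hits)
    if (length(config)) out$config <- config
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("##gff-version 3", cfg_lines), con)
    if (nrow(hits)) {
      attrs <- sprintf("ID=%s_%s_%d;Name=%s;active=%s%s",
                       hits$protein_id, hits$domain_type, seq_len(nrow(hits)),
                       hits$domain_type, tolower(as.character(hits$active)),
                       ifelse(is.na(hits$reason) | hits$reason == "", "",
                              paste0(";note=", hits$reason)))
      gff <- data.frame(seqid = hits$protein_id, source = "pksline",
                        type = "polypeptide_domain",
                        start = hits$start + 1L, end = hits$end,
                        score = round(hits$score, 2), strand = ".",
                        phase = ".", attributes = attrs)
      stopifnot(all(gff$start >= 1L), all(gff$end >= gff$start))
      write.table(gff, con, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(path)
}

#' Describe an observed polyketide chemotype
#'
#' Encodes the per-carbon facts of an elucidated structure for
#' reconciliation with a prediction: hydroxyl positions and
#' configurations, double bonds (a bond labelled `n` joins carbons `n`
#' and `n + 1`), methyl branch positions, and the starter unit.
#'
#' @param carbon_count Number of backbone carbons.
#' @param hydroxyls Data frame with columns `carbon` and `config`
#'   (`"R"`, `"S"` or `"unknown"`).
#' @param double_bonds Data frame with columns `delta` and `geometry`
#'   (`"E"` or `"Z"`).
#' @param methyl_branches Integer vector of branch carbons.
#' @param starter_unit `"acetate"` or `"propionate"`.
#' @return An object of class `observed_chemotype`.
#' @export
observed_chemotype <- function(carbon_count, hydroxyls = NULL,
                               double_bonds = NULL, methyl_branches = integer(),
                               starter_unit = c("acetate", "propionate")) {
  starter_unit <- match.arg(starter_unit)
  carbon_count <- as.integer(carbon_count)
  stopifnot(carbon_count >= 2L)
  if (is.null(hydroxyls))
    hydroxyls <- data.frame(carbon = integer(), config = character())
  if (is.null(double_bonds))
    double_bonds <- data.frame(delta = integer(), geometry = character())
  hydroxyls$carbon <- as.integer(hydroxyls$carbon)
  double_bonds$delta <- as.integer(double_bonds$delta)
  methyl_branches <- sort(as.integer(methyl_branches))
  stopifnot(all(hydroxyls$config %in% c("R", "S", "unknown")),
            all(double_bonds$geometry %in% c("E", "Z")))
  pos <- c(hydroxyls$carbon, methyl_branches)
  if (any(pos < 1L | pos > carbon_count))
    stop("observed_chemotype: position outside [1, carbon_count]")
  if (any(double_bonds$delta < 1L | double_bonds$delta + 1L > carbon_count))
    stop("observed_chemotype: double bond outside backbone")
  # a backbone carbon is either hydroxylated or part of a double bond;
  # methyl branches are substituents and may sit on bond carbons
  claimed <- c(hydroxyls$carbon, double_bonds$delta, double_bonds$delta + 1L)
  if (anyDuplicated(claimed) || anyDuplicated(methyl_branches))
    stop("observed_chemotype: a carbon appears in more than one state list")
  structure(list(carbon_count = carbon_count, hydroxyls = hydroxyls,
                 double_bonds = double_bonds,
                 methyl_branches = methyl_branches,
                 starter_unit = starter_unit),
            class = "observed_chemotype")
}

#' @export
print.observed_chemotype <- function(x, ...) {
  cat(sprintf("<observed_chemotype> C%d backbone, starter %s\n",
              x$carbon_count, x$starter_unit))
  cat(sprintf("  hydroxyls: %s\n",
              paste(sprintf("C%d(%s)", x$hydroxyls$carbon,
                            x$hydroxyls$config), collapse = " ")))
  cat(sprintf("  double bonds: %s\n",
              paste(sprintf("Δ%d(%s)", x$double_bonds$delta,
                            x$double_bonds$geometry), collapse = " ")))
  cat(sprintf("  methyl branches: %s\n",
              paste0("C", x$methyl_branches, collapse = " ")))
  invisible(x)
}
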