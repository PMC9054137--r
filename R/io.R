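# Readers and writers for the external formats the pipeline touches:
# PAF alignment records, BED origin annotations, FASTA references,
# suppressivity tables, and the TSV/JSON report pair.
# All coordinates are 0-based half-open internally (PAF/BED native).

#' Read long-read alignment records from a PAF file
#'
#' Parses the 12 mandatory PAF columns (minimap2 dialect) into a tidy
#' alignment table, one row per collinear read-to-reference alignment
#' segment. Rows are grouped by read and ordered by position in the read,
#' which is the order downstream breakpoint extraction relies on. Optional
#' SAM-style tag columns beyond column 12 are ignored; CIGAR strings are
#' never used, only interval endpoints.
#'
#' A mapping quality of 255 means "unavailable" in the PAF/SAM convention;
#' such rows are retained but flagged (`mapq_unavailable`) and will fail the
#' default quality filter in [filter_alignments()].
#'
#' @param path Path to a PAF file.
#' @param genome Optional reference genome tibble (see [read_reference()]);
#'   when supplied, rows whose reference interval falls outside the genome
#'   are rejected with a warning.
#' @return A tibble with columns `read_id`, `read_length`, `read_start`,
#'   `read_end`, `strand`, `ref_name`, `ref_start`, `ref_end`, `mapq`,
#'   `mapq_unavailable`, sorted by `read_id` then `read_start`.
#' @export
#' @examples
#' paf <- tempfile(fileext = ".paf")
#' writeLines("r1\t500\t0\t500\t+\tchrM\t85779\t100\t600\t480\t500\t60", paf)
#' read_alignments(paf)
read_alignments <- function(path, genome = NULL) {
  if (!file.exists(path)) {
    abort(paste0("PAF file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_alignments())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, length, integer(1)) >= 12L
  if (any(!ok)) {
    warn(sprintf("dropped %d malformed PAF row(s) (fewer than 12 fields)",
                 sum(!ok)))
    fields <- fields[ok]
  }
  if (length(fields) == 0L) {
    return(empty_alignments())
  }
  mat <- do.call(rbind, lapply(fields, `[`, 1:12))
  aln <- tibble(
    read_id     = mat[, 1],
    read_length = suppressWarnings(as.integer(mat[, 2])),
    read_start  = suppressWarnings(as.integer(mat[, 3])),
    read_end    = suppressWarnings(as.integer(mat[, 4])),
    strand      = mat[, 5],
    ref_name    = mat[, 6],
    ref_length  = suppressWarnings(as.integer(mat[, 7])),
    ref_start   = suppressWarnings(as.integer(mat[, 8])),
    ref_end     = suppressWarnings(as.integer(mat[, 9])),
    mapq        = suppressWarnings(as.integer(mat[, 12]))
  )
  bad <- !complete.cases(aln[c("read_length", "read_start", "read_end",
                               "ref_start", "ref_end", "mapq")]) |
    !(aln$strand %in% c("+", "-")) |
    aln$read_start >= aln$read_end | aln$ref_start >= aln$ref_end
  if (!is.null(genome)) {
    bad <- bad | aln$ref_end > genome$length[[1]] | aln$ref_start < 0L
  }
  if (any(bad)) {
    warn(sprintf("rejected %d PAF row(s) with invalid intervals", sum(bad)))
    aln <- aln[!bad, ]
  }
  aln %>%
    mutate(mapq_unavailable = .data$mapq == 255L) %>%
    select(-"ref_length") %>%
    arrange(.data$read_id, .data$read_start)
}

empty_alignments <- function() {
  tibble(
    read_id = character(), read_length = integer(),
    read_start = integer(), read_end = integer(), strand = character(),
    ref_name = character(), ref_start = integer(), ref_end = integer(),
    mapq = integer(), mapq_unavailable = logical()
  )
}

#' Write alignment records to PAF
#'
#' Inverse of [read_alignments()]; emits the 12 mandatory columns. The
#' number-of-matches and block-length columns are filled with the segment
#' length since the pipeline carries no base-level information.
#'
#' @param alignments Alignment tibble.
#' @param path Output path.
#' @param genome Optional reference genome tibble supplying name and length
#'   for columns 6-7.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(alignments, path, genome = NULL) {
  ref_name <- if (!is.null(genome)) genome$name[[1]] else
    (alignments$ref_name %||% "chrM")
  ref_len <- if (!is.null(genome)) genome$length[[1]] else
    max(alignments$ref_end, 0L)
  seg_len <- alignments$ref_end - alignments$ref_start
  rows <- paste(
    alignments$read_id, alignments$read_length,
    alignments$read_start, alignments$read_end, alignments$strand,
    ref_name, ref_len,
    alignments$ref_start, alignments$ref_end,
    seg_len, seg_len, alignments$mapq,
    sep = "\t"
  )
  writeLines(rows, path)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Read replication-origin annotations from a BED file
#'
#' Accepts BED3 or richer. Yeast mtDNA carries eight homologous, GC-rich
#' replication origins; this is the expected annotation input, but any
#' interval set works. Rows with `start >= end` are rejected.
#'
#' @param path Path to a BED file (3+ columns, 0-based half-open).
#' @param genome Optional genome tibble; intervals extending beyond the
#'   genome are rejected with a warning.
#' @return Tibble with columns `name`, `start`, `end`, `strand`.
#' @export
read_origins <- function(path, genome = NULL) {
  if (!file.exists(path)) abort(paste0("BED file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    return(tibble(name = character(), start = integer(), end = integer(),
                  strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- vapply(fields, length, integer(1))
  if (any(n_col < 3L)) abort("BED rows must have at least 3 columns")
  ori <- tibble(
    start  = suppressWarnings(as.integer(vapply(fields, `[`, "", 2))),
    end    = suppressWarnings(as.integer(vapply(fields, `[`, "", 3))),
    name   = ifelse(n_col >= 4L, vapply(fields, function(f) f[4] %||% NA_character_, ""), NA_character_),
    strand = ifelse(n_col >= 6L, vapply(fields, function(f) f[6] %||% "+", ""), "+")
  )
  ori$name[is.na(ori$name)] <- paste0("ori", seq_len(nrow(ori)))[is.na(ori$name)]
  bad <- is.na(ori$start) | is.na(ori$end) | ori$start >= ori$end | ori$start < 0L
  if (!is.null(genome)) bad <- bad | ori$end > genome$length[[1]]
  if (any(bad)) {
    warn(sprintf("rejected %d BED row(s) with invalid intervals", sum(bad)))
    ori <- ori[!bad, ]
  }
  select(ori, "name", "start", "end", "strand")
}

#' Read a reference genome from FASTA
#'
#' Reads the first (or named) sequence of a FASTA file into the one-row
#' genome tibble used throughout the package. The yeast mitochondrial
#' reference (85,779 bp) is the motivating case; it is biologically
#' circular, but all coordinates in the package are linear unless a
#' function exposes a `circular` option.
#'
#' @param path FASTA path.
#' @param name Optional sequence name to select.
#' @param circular Mark the genome as circular (annotation only).
#' @return Tibble with columns `name`, `length`, `sequence`, `circular`.
#' @export
read_reference <- function(path, name = NULL, circular = TRUE) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  seqs <- Biostrings::readDNAStringSet(path)
  nms <- sub("\\s.*$", "", names(seqs))
  idx <- if (is.null(name)) 1L else match(name, nms)
  if (is.na(idx)) abort(paste0("sequence not found in FASTA: ", name))
  reference_genome(nms[idx], as.character(seqs[[idx]]), circular = circular)
}

#' Construct a reference genome record
#'
#' @param name Sequence name.
#' @param sequence Nucleotide string (A/C/G/T/N).
#' @param circular Is the molecule circular?
#' @return One-row tibble with columns `name`, `length`, `sequence`,
#'   `circular`.
#' @export
reference_genome <- function(name, sequence, circular = TRUE) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) abort("sequence alphabet must be A/C/G/T/N")
  tibble(name = name, length = nchar(sequence), sequence = sequence,
         circular = circular)
}

#' Write a reference genome to FASTA
#' @param genome Genome tibble.
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_reference <- function(genome, path, width = 70L) {
  seqs <- Biostrings::DNAStringSet(setNames(genome$sequence[[1]],
                                            genome$name[[1]]))
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Read per-colony suppressivity measurements
#'
#' Expects a TSV with at least columns `sample` and `suppressivity`
#' (fraction of Petite progeny in a cross against a Grande tester, in
#' `[0, 1]`); an optional `n_colonies` column records how many colonies were
#' scored.
#'
#' @param path TSV path.
#' @return Tibble with columns `sample`, `suppressivity`, `n_colonies`.
#' @export
read_suppressivity <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample", "suppressivity") %in% names(tab))) {
    abort("suppressivity table needs columns 'sample' and 'suppressivity'")
  }
  if (any(tab$suppressivity < 0 | tab$suppressivity > 1, na.rm = TRUE)) {
    abort("suppressivity must lie in [0, 1]")
  }
  if (!"n_colonies" %in% names(tab)) tab$n_colonies <- NA_integer_
  as_tibble(tab[c("sample", "suppressivity", "n_colonies")])
}

#' Write pipeline results as a TSV/JSON report
#'
#' Emits `breakpoints.tsv` (one row per retained cluster), `frequencies.tsv`
#' (one row per structure) and `structures.json` (lossless nested record of
#' the structure table, including the per-structure alignment lists) under
#' `dir`. [read_report()] round-trips the JSON back into the structure
#' tibble.
#'
#' @param structures Structure tibble (see [reconstruct_structures()]).
#' @param clusters Cluster tibble (see [cluster_breakpoints()]).
#' @param frequencies Frequency tibble (see [structure_frequencies()]), or
#'   `NULL`.
#' @param dir Output directory, created if needed.
#' @return The directory, invisibly.
#' @export
write_report <- function(structures, clusters, frequencies = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cl <- clusters %>%
    select(any_of(c("cluster_id", "kind", "centroid_a", "centroid_b",
                    "sd_a", "sd_b", "n_signals", "n_reads",
                    "P", "N", "PR", "NR", "retained")))
  readr::write_tsv(cl, file.path(dir, "breakpoints.tsv"))
  if (!is.null(frequencies)) {
    readr::write_tsv(frequencies, file.path(dir, "frequencies.tsv"))
  }
  recs <- purrr::pmap(structures, function(...) {
    row <- list(...)
    row$alignments <- as.list(as.data.frame(row$alignments))
    row$clusters <- as.list(row$clusters)
    row
  })
  jsonlite::write_json(recs, file.path(dir, "structures.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read back a structure report written by [write_report()]
#' @param dir Report directory.
#' @return Structure tibble.
#' @export
read_report <- function(dir) {
  recs <- jsonlite::read_json(file.path(dir, "structures.json"))
  rows <- purrr::map(recs, function(r) {
    aln <- as_tibble(lapply(r$alignments, unlist))
    if (nrow(aln)) {
      aln$ref_start <- as.numeric(aln$ref_start)
      aln$ref_end <- as.numeric(aln$ref_end)
    }
    scalars <- r[setdiff(names(r), c("alignments", "clusters"))]
    scalars <- lapply(scalars, function(x) if (is.null(x)) NA else x)
    out <- as_tibble(scalars)
    out$alignments <- list(aln)
    out$clusters <- list(as.numeric(unlist(r$clusters)))
    out
  })
  bind_rows(rows)
}

#' @importFrom dplyr any_of
NULL
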