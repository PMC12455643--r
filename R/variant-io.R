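#' @importFrom rlang .data
NULL

MUTATION_TYPES <- c("SNP", "INS", "DEL")

RECORD_COLS <- c("mutation_id", "type", "seq_id", "position", "detail",
                 "isolate_id", "frequency")

#' Stable mutation identifier
#'
#' Mutations are keyed by sequence, position and allele change so that the
#' same event called in different isolates shares one identifier.
#'
#' @param seq_id,position,type,detail Vectors describing the mutation.
#' @return Character vector of identifiers.
#' @export
mutation_key <- function(seq_id, position, type, detail) {
  paste(seq_id, position, type, detail, sep = ":")
}

validate_records <- function(records, where = "records") {
  missing_cols <- setdiff(RECORD_COLS, names(records))
  if (length(missing_cols) > 0) {
    stop(where, " missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad_line <- function(i, msg) {
    stop(where, ", line ", i, ": ", msg, call. = FALSE)
  }
  pos <- suppressWarnings(as.integer(records$position))
  freq <- suppressWarnings(as.numeric(records$frequency))
  for (i in seq_len(nrow(records))) {
    if (is.na(pos[i]) || pos[i] < 1) bad_line(i, "position must be an integer >= 1")
    if (is.na(freq[i]) || freq[i] < 0 || freq[i] > 1) {
      bad_line(i, paste0("frequency must be in [0, 1], got '",
                         records$frequency[i], "'"))
    }
    if (!(records$type[i] %in% MUTATION_TYPES)) {
      bad_line(i, paste0("unknown mutation type '", records$type[i], "'"))
    }
    if (records$type[i] == "DEL") {
      len <- suppressWarnings(as.integer(records$detail[i]))
      if (is.na(len) || len < 1) bad_line(i, "DEL detail must be a length >= 1")
    }
  }
  tibble::tibble(
    mutation_id = as.character(records$mutation_id),
    type = as.character(records$type),
    seq_id = as.character(records$seq_id),
    position = pos,
    detail = as.character(records$detail),
    isolate_id = as.character(records$isolate_id),
    frequency = freq
  )
}

#' Read a mutation frequency table
#'
#' Reads a TSV of per-isolate mutation observations as produced by
#' polymorphism-mode variant calling (one row per mutation per isolate, with
#' the fraction of reads supporting the call). Rows violating the record
#' invariants are rejected with their line number.
#'
#' @param path Path to a TSV with header columns `mutation_id`, `type`,
#'   `seq_id`, `position`, `detail`, `isolate_id`, `frequency`.
#' @return A tibble of typed mutation records.
#' @export
read_frequency_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    missing_cols <- setdiff(RECORD_COLS, names(raw))
    if (length(missing_cols) > 0) {
      stop(path, " missing column(s): ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    }
    return(validate_records(raw[0, ], where = path))
  }
  validate_records(raw, where = path)
}

#' Write a mutation frequency table
#'
#' Frequencies are serialized with 4 decimal places, matching the precision
#' of polymorphism-mode read-support percentages (e.g. 74.5% -> 0.7450).
#'
#' @param records A data frame of mutation records (see
#'   [read_frequency_table()] for the columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(records, path) {
  records <- validate_records(records)
  out <- records
  out$frequency <- sprintf("%.4f", records$frequency)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a minimal genome-diff dialect file
#'
#' Parses the tab-delimited mutation lines of a breseq-style genome-diff
#' file: `TYPE  id  parent_ids  seq_id  position  detail...  frequency=F`.
#' Header lines starting with `#` are ignored. Only SNP, INS and DEL records
#' are supported; other record types (MOB, AMP, evidence lines, ...) are
#' skipped with a single warning giving their count (also available as the
#' `skipped` attribute of the result).
#'
#' @param path Path to the genome-diff file.
#' @param isolate_id Isolate the file describes; genome-diff files carry no
#'   sample column. Defaults to the file name without extension.
#' @return A tibble of mutation records with a `skipped` attribute.
#' @export
read_gd <- function(path, isolate_id = NULL) {
  if (is.null(isolate_id)) {
    isolate_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  skipped <- 0L
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    type <- fields[1]
    if (!(type %in% MUTATION_TYPES)) {
      skipped <- skipped + 1L
      next
    }
    if (length(fields) < 6) {
      stop(path, ": malformed ", type, " line (", length(fields), " fields): ",
           lines[i], call. = FALSE)
    }
    freq_field <- fields[length(fields)]
    if (!grepl("^frequency=", freq_field)) {
      stop(path, ": last field of a mutation line must be frequency=F, got '",
           freq_field, "'", call. = FALSE)
    }
    freq <- suppressWarnings(as.numeric(sub("^frequency=", "", freq_field)))
    if (is.na(freq)) {
      stop(path, ": malformed frequency key '", freq_field, "'", call. = FALSE)
    }
    detail <- paste(fields[6:(length(fields) - 1)], collapse = "\t")
    rows[[i]] <- tibble::tibble(
      mutation_id = fields[2], type = type, seq_id = fields[4],
      position = fields[5], detail = detail,
      isolate_id = isolate_id, frequency = freq
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (skipped > 0) {
    warning("skipped ", skipped, " unsupported genome-diff record(s) in ", path,
            call. = FALSE)
  }
  out <- if (length(rows) == 0) {
    tibble::tibble(mutation_id = character(), type = character(),
                   seq_id = character(), position = character(),
                   detail = character(), isolate_id = character(),
                   frequency = numeric())
  } else {
    dplyr::bind_rows(rows)
  }
  out <- validate_records(out, where = path)
  attr(out, "skipped") <- skipped
  out
}

#' Write mutation records as a minimal genome-diff dialect file
#'
#' The inverse of [read_gd()]: one mutation line per record, `parent_ids`
#' written as `.`, frequencies with 4 decimals. Genome-diff files describe a
#' single sample, so all records must share one `isolate_id`.
#'
#' @param records A data frame of mutation records for one isolate.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gd <- function(records, path) {
  records <- validate_records(records)
  if (length(unique(records$isolate_id)) > 1) {
    stop("genome-diff files describe one sample; got isolates: ",
         paste(unique(records$isolate_id), collapse = ", "), call. = FALSE)
  }
  lines <- c("#=GENOME_DIFF\t1.0")
  if (nrow(records) > 0) {
    lines <- c(lines, paste(
      records$type, records$mutation_id, ".", records$seq_id,
      records$position, records$detail,
      sprintf("frequency=%.4f", records$frequency),
      sep = "\t"
    ))
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read gene annotations from GFF3 or BED
#'
#' Ingests gene intervals and unifies them to 1-based inclusive coordinates
#' (the GFF3 and genome-diff convention). BED's 0-based half-open intervals
#' are converted on import. Parsing is delegated to the `rtracklayer`
#' import machinery.
#'
#' @param path Path to the annotation file.
#' @param format `"gff3"` or `"bed"`. Guessed from the file extension when
#'   omitted.
#' @return A tibble with columns `gene_id`, `seq_id`, `start`, `end`,
#'   `strand` (`+`/`-`; features without strand become `+`).
#' @export
read_gene_annotations <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(sub(".*\\.", "", path))
    format <- if (ext %in% c("bed")) "bed" else "gff3"
  }
  format <- match.arg(tolower(format), c("gff3", "bed"))
  gr <- rtracklayer::import(path, format = format)
  meta <- S4Vectors::mcols(gr)

  if (format == "gff3") {
    if ("type" %in% names(meta) && any(meta$type == "gene")) {
      gr <- gr[meta$type == "gene"]
      meta <- S4Vectors::mcols(gr)
    }
    gene_id <- rep(NA_character_, length(gr))
    for (col in c("locus_tag", "ID", "Name", "gene_id", "gene")) {
      if (col %in% names(meta)) {
        val <- as.character(meta[[col]])
        gene_id <- ifelse(is.na(gene_id) & !is.na(val), val, gene_id)
      }
    }
  } else {
    gene_id <- if ("name" %in% names(meta)) as.character(meta$name) else NA_character_
  }
  if (any(is.na(gene_id))) {
    stop(path, ": could not determine a gene_id for every feature", call. = FALSE)
  }
  if (any(GenomicRanges::width(gr) < 1)) {
    stop(path, ": empty interval (start == end in BED, or inverted coordinates)",
         call. = FALSE)
  }
  ann <- tibble::tibble(
    gene_id = gene_id,
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  ann$strand[!ann$strand %in% c("+", "-")] <- "+"
  dup <- duplicated(ann[, c("gene_id", "seq_id")])
  if (any(dup)) {
    stop(path, ": duplicate gene_id on one sequence: ",
         paste(unique(ann$gene_id[dup]), collapse = ", "), call. = FALSE)
  }
  if (any(ann$start < 1) || any(ann$start > ann$end)) {
    stop(path, ": invalid coordinates (need 1 <= start <= end)", call. = FALSE)
  }
  ann
}

#' Assign mutations to genes by positional overlap
#'
#' A mutation is assigned to a gene when its genomic footprint (a single base
#' for SNP/INS, `[position, position + length - 1]` for DEL) overlaps the
#' gene's `[start, end]` interval. Ties between overlapping genes are broken
#' by smaller gene start, then lexicographic `gene_id`. Mutations overlapping
#' no gene are labelled `"intergenic"`. Strand is ignored: the assignment is
#' purely positional.
#'
#' @param records A data frame of mutation records.
#' @param annotations A gene annotation tibble (see
#'   [read_gene_annotations()]).
#' @return A tibble with one row per unique `mutation_id`: `mutation_id`,
#'   `gene_id`.
#' @export
assign_genes <- function(records, annotations) {
  records <- validate_records(records)
  muts <- dplyr::distinct(records, .data$mutation_id, .data$type,
                          .data$seq_id, .data$position, .data$detail)
  if (nrow(muts) == 0) {
    return(tibble::tibble(mutation_id = character(), gene_id = character()))
  }
  del_len <- ifelse(muts$type == "DEL",
                    suppressWarnings(as.integer(muts$detail)), 1L)
  mut_gr <- GenomicRanges::GRanges(
    seqnames = muts$seq_id,
    ranges = IRanges::IRanges(start = muts$position,
                              end = muts$position + del_len - 1L)
  )
  gene_gr <- GenomicRanges::GRanges(
    seqnames = annotations$seq_id,
    ranges = IRanges::IRanges(start = annotations$start, end = annotations$end)
  )
  hits <- GenomicRanges::findOverlaps(mut_gr, gene_gr, ignore.strand = TRUE)
  gene_id <- rep("intergenic", nrow(muts))
  if (length(hits) > 0) {
    ht <- tibble::tibble(
      mut = S4Vectors::queryHits(hits),
      gene = annotations$gene_id[S4Vectors::subjectHits(hits)],
      gstart = annotations$start[S4Vectors::subjectHits(hits)]
    )
    best <- ht |>
      dplyr::arrange(.data$mut, .data$gstart, .data$gene) |>
      dplyr::distinct(.data$mut, .keep_all = TRUE)
    gene_id[best$mut] <- best$gene
  }
  tibble::tibble(mutation_id = muts$mutation_id, gene_id = gene_id)
}
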