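#' Read and validate a sample sheet
#'
#' The sample sheet is a tab-separated table with one row per sequencing
#' library and columns `sample_id`, `tissue` (one of `meiocyte`, `anther`,
#' `seedling`), `replicate` (positive integer), `library_total` (total
#' genome-aligned reads in the library; the RPM denominator) and optionally
#' `is_pseudo` (TRUE for a column produced by [split_pseudoreplicates()]).
#'
#' @param path path to a TSV file.
#' @return A validated tibble.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, show_col_types = FALSE)
  validate_sample_sheet(sheet)
}

#' @rdname read_sample_sheet
#' @param samples a data frame to validate in place.
#' @export
validate_sample_sheet <- function(samples) {
  samples <- as_tibble(samples)
  need <- c("sample_id", "tissue", "replicate", "library_total")
  missing <- setdiff(need, names(samples))
  if (length(missing) > 0) {
    abort(paste0("sample sheet is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"is_pseudo" %in% names(samples)) samples$is_pseudo <- FALSE
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id)) {
    abort(paste0("duplicate sample_id in sample sheet: ",
                 paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
                       collapse = ", ")))
  }
  bad <- setdiff(unique(samples$tissue), TISSUES)
  if (length(bad) > 0) {
    abort(paste0("unknown tissue(s): ", paste(bad, collapse = ", "),
                 "; expected ", paste(TISSUES, collapse = "/")))
  }
  if (any(samples$library_total <= 0)) {
    abort(paste0("library_total must be > 0; offending sample(s): ",
                 paste(samples$sample_id[samples$library_total <= 0],
                       collapse = ", ")))
  }
  if (any(samples$replicate < 1 | samples$replicate != round(samples$replicate))) {
    abort("replicate must be a positive integer")
  }
  samples
}

#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(samples, path) {
  readr::write_tsv(validate_sample_sheet(samples), path)
  invisible(path)
}

#' Read and validate a gene-by-sample count table
#'
#' Counts are stored as a TSV with a header row, a first column `gene_id` and
#' one non-negative integer column per library. The table is validated against
#' a sample sheet and its columns reordered to the sheet order.
#'
#' @param path path to the counts TSV.
#' @param samples a sample sheet (tibble from [read_sample_sheet()]) or the
#'   path to one.
#' @return A tibble with `gene_id` plus one integer column per sample.
#' @export
read_counts <- function(path, samples) {
  if (is.character(samples)) samples <- read_sample_sheet(samples)
  counts <- readr::read_tsv(path, show_col_types = FALSE)
  validate_counts(counts, samples)
}

#' @rdname read_counts
#' @param counts a counts data frame to validate against `samples`.
#' @export
validate_counts <- function(counts, samples) {
  samples <- validate_sample_sheet(samples)
  counts <- as_tibble(counts)
  if (!identical(names(counts)[1], "gene_id")) {
    abort("counts table must have 'gene_id' as its first column")
  }
  missing <- setdiff(samples$sample_id, names(counts))
  if (length(missing) > 0) {
    abort(paste0("counts table is missing sample column(s): ",
                 paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(counts)[-1], samples$sample_id)
  if (length(extra) > 0) {
    abort(paste0("counts table has column(s) absent from the sample sheet: ",
                 paste(extra, collapse = ", ")))
  }
  if (anyDuplicated(counts$gene_id)) {
    abort(paste0("duplicate gene_id in counts table: ",
                 paste(unique(counts$gene_id[duplicated(counts$gene_id)]),
                       collapse = ", ")))
  }
  for (sid in samples$sample_id) {
    v <- counts[[sid]]
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad) > 0) {
      abort(sprintf(
        "counts must be non-negative integers; first offender: gene %s, sample %s (value %s)",
        counts$gene_id[bad[1]], sid, format(v[bad[1]])))
    }
    if (!is.integer(v) && max(v, 0) < .Machine$integer.max) {
      counts[[sid]] <- as.integer(v)
    }
  }
  counts[, c("gene_id", samples$sample_id)]
}

#' @rdname read_counts
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read gene models from GFF3 or BED, optionally labelling TE genes
#'
#' Gene models are carried internally with 1-based inclusive coordinates (the
#' TAIR convention). BED input is 0-based half-open; the conversion happens at
#' the parsing boundary (via `rtracklayer`). For GFF3, only rows of type
#' `gene` are kept (all rows if no `type` column is present) and the gene
#' identifier is taken from the `ID` (falling back to `Name`) attribute. An
#' optional TE table (TSV: `gene_id`, `transposon_id`, `family`,
#' `superfamily`) marks matching genes as `biotype = "te"`; TE rows whose
#' `gene_id` is absent from the gene models are skipped with a warning.
#'
#' @param path path to a `.gff`/`.gff3` or `.bed` file.
#' @param te_table optional TE annotation: a data frame or TSV path.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (`+`, `-` or `.`), `biotype` (`nuclear`, `te`, `mgi` or `other`),
#'   `te_family`, `te_superfamily`.
#' @export
read_annotation <- function(path, te_table = NULL) {
  fmt <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (fmt == "gff3" && "type" %in% names(mc) && any(mc$type == "gene")) {
    keep <- mc$type == "gene"
    gr <- gr[keep]
    mc <- mc[keep, , drop = FALSE]
  }
  gene_id <- if (fmt == "bed") {
    as.character(mc$name)
  } else if ("ID" %in% names(mc) && !all(is.na(mc$ID))) {
    as.character(mc$ID)
  } else if ("Name" %in% names(mc)) {
    as.character(mc$Name)
  } else {
    abort("GFF3 gene rows carry neither an ID nor a Name attribute")
  }
  ann <- tibble(
    gene_id = gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = chartr("*", ".", as.character(GenomicRanges::strand(gr))),
    biotype = if ("biotype" %in% names(mc)) as.character(mc$biotype) else "nuclear",
    te_family = NA_character_,
    te_superfamily = NA_character_
  )
  ann$biotype[is.na(ann$biotype)] <- "nuclear"
  if (any(ann$start > ann$end)) {
    abort("gene model with start > end in annotation")
  }
  if (!is.null(te_table)) {
    if (is.character(te_table)) te_table <- read_te_table(te_table)
    unknown <- setdiff(te_table$gene_id, ann$gene_id)
    if (length(unknown) > 0) {
      warn(paste0("TE table rows skipped (gene_id not in gene models): ",
                  paste(unknown, collapse = ", ")))
      te_table <- te_table[!te_table$gene_id %in% unknown, ]
    }
    idx <- match(te_table$gene_id, ann$gene_id)
    ann$biotype[idx] <- "te"
    ann$te_family[idx] <- as.character(te_table$family)
    ann$te_superfamily[idx] <- as.character(te_table$superfamily)
  }
  ann
}

#' @rdname read_annotation
#' @param annotation a gene-model tibble as returned by [read_annotation()].
#' @export
write_annotation <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start, end = annotation$end),
    strand = chartr(".", "*", annotation$strand)
  )
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- annotation$gene_id
  S4Vectors::mcols(gr)$Name <- annotation$gene_id
  S4Vectors::mcols(gr)$biotype <- annotation$biotype
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname read_annotation
#' @export
read_te_table <- function(path) {
  te <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("gene_id", "transposon_id", "family", "superfamily")
  missing <- setdiff(need, names(te))
  if (length(missing) > 0) {
    abort(paste0("TE table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  te
}

#' @rdname read_annotation
#' @param te a TE table (`gene_id`, `transposon_id`, `family`, `superfamily`).
#' @export
write_te_table <- function(te, path) {
  readr::write_tsv(te, path)
  invisible(path)
}
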