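#' Readers, writers and validators for the pipeline's tables
#'
#' All tables are plain tibbles with a documented column contract, read from and
#' written to TSV. Readers are strict: every invariant of the in-memory type is
#' enforced at load time, and malformed cells are reported by gene/sample so
#' problems in large consortium-style matrices are locatable.
#'
#' Column contracts:
#' \describe{
#'   \item{expression}{`gene` column plus one numeric column per sample; values
#'     are log2-scale expression. No duplicate genes or samples; all finite
#'     (missing values are a load-time error, not imputed).}
#'   \item{copy number}{same shape; integer GISTIC-style thresholded calls in
#'     \{-2, -1, 0, 1, 2\} (homozygous deletion, heterozygous loss, neutral,
#'     gain, amplification).}
#'   \item{mutations}{MAF-dialect columns `Hugo_Symbol`, `Tumor_Sample_Barcode`,
#'     `Chromosome`, `Start_Position` (1-based bp), `Reference_Allele`,
#'     `Tumor_Seq_Allele2`, `Variant_Classification`; renamed on load to
#'     `gene`, `sample`, `chrom`, `position`, `ref`, `alt`, `variant_class`.}
#'   \item{annotation}{`gene`, `chrom`, `start`, `end` (1-based inclusive bp),
#'     `strand` in \{+,-\}; `length = end - start` is derived on load.}
#'   \item{clinical}{`patient`, per-endpoint `os_time`/`os_event`,
#'     `dss_time`/`dss_event`, `pfs_time`/`pfs_event` (days; event 1, censored
#'     0), `treatment` label, and `mets`: metastasis records encoded
#'     `"site:days;site:days"` in the file and parsed to a list-column of
#'     tibbles in memory (see [metastasis_events()]).}
#'   \item{fusions}{`sample`, `gene_a`, `gene_b`, `chrom_a`, `pos_a`, `chrom_b`,
#'     `pos_b`, `microhomology`, `insertion` (bp; never both positive at one
#'     junction).}
#' }
#'
#' @param path Path to a TSV file.
#' @param x Table to write.
#' @param bed_coords For [read_annotation()]: if `TRUE` the file is 0-based
#'   half-open (BED-like) and starts are converted to the internal 1-based
#'   convention (`start + 1`).
#' @return Readers return validated tibbles; writers return `path` invisibly.
#' @name rin_io
NULL

strict_read_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE, comment = "#")
}

# parse the sample columns of a genes-x-samples table, reporting the offending
# cell on failure; `checker` validates the parsed numbers
parse_matrix_cells <- function(raw, what, checker) {
  if (names(raw)[1] != "gene") {
    abort(paste0(what, ": first column must be named 'gene', got '", names(raw)[1], "'"))
  }
  samples <- names(raw)[-1]
  if (length(samples) == 0) abort(paste0(what, ": no sample columns"))
  out <- raw["gene"]
  for (s in samples) {
    v <- suppressWarnings(as.numeric(raw[[s]]))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      abort(paste0(
        what, ": cannot parse cell at gene '", raw$gene[bad[1]],
        "', sample '", s, "' (value '",
        as.character(raw[[s]][bad[1]]), "')"
      ))
    }
    checker(v, raw$gene, s)
    out[[s]] <- v
  }
  as_tibble(out)
}

#' @rdname rin_io
#' @export
read_expression <- function(path) {
  raw <- strict_read_tsv(path)
  x <- parse_matrix_cells(raw, "expression", function(v, genes, s) {
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      abort(paste0("expression: non-finite value at gene '", genes[bad[1]],
                   "', sample '", s, "'"))
    }
  })
  validate_expression(x)
}

#' @rdname rin_io
#' @export
validate_expression <- function(x) {
  stopifnot(is.data.frame(x))
  if (!"gene" %in% names(x)) abort("expression: missing 'gene' column")
  dup <- x$gene[duplicated(x$gene)]
  if (length(dup) > 0) {
    abort(paste0("expression: duplicate gene symbols: ",
                 paste(unique(dup), collapse = ", ")))
  }
  samples <- setdiff(names(x), "gene")
  if (anyDuplicated(samples)) abort("expression: duplicate sample IDs")
  for (s in samples) {
    if (!is.numeric(x[[s]]) || any(!is.finite(x[[s]]))) {
      abort(paste0("expression: sample '", s, "' has non-finite or non-numeric values"))
    }
  }
  as_tibble(x)
}

#' @rdname rin_io
#' @export
write_expression <- function(x, path) {
  validate_expression(x)
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname rin_io
#' @export
read_copy_number <- function(path) {
  raw <- strict_read_tsv(path)
  x <- parse_matrix_cells(raw, "copy number", function(v, genes, s) {
    bad <- which(!(v %in% c(-2, -1, 0, 1, 2)))
    if (length(bad) > 0) {
      abort(paste0("copy number: call outside {-2,...,2} at gene '",
                   genes[bad[1]], "', sample '", s, "' (value ",
                   v[bad[1]], ")"))
    }
  })
  x <- mutate(x, across(-"gene", as.integer))
  validate_copy_number(x)
}

#' @rdname rin_io
#' @export
validate_copy_number <- function(x) {
  stopifnot(is.data.frame(x))
  if (!"gene" %in% names(x)) abort("copy number: missing 'gene' column")
  if (anyDuplicated(x$gene)) abort("copy number: duplicate gene symbols")
  samples <- setdiff(names(x), "gene")
  if (anyDuplicated(samples)) abort("copy number: duplicate sample IDs")
  for (s in samples) {
    if (any(!x[[s]] %in% c(-2L, -1L, 0L, 1L, 2L))) {
      abort(paste0("copy number: sample '", s, "' has calls outside {-2,...,2}"))
    }
  }
  as_tibble(x)
}

#' @rdname rin_io
#' @export
write_copy_number <- function(x, path) {
  validate_copy_number(x)
  readr::write_tsv(x, path)
  invisible(path)
}

maf_required_cols <- c(
  "Hugo_Symbol", "Tumor_Sample_Barcode", "Chromosome", "Start_Position",
  "Reference_Allele", "Tumor_Seq_Allele2", "Variant_Classification"
)

#' @rdname rin_io
#' @export
read_maf <- function(path) {
  raw <- strict_read_tsv(path)
  missing <- setdiff(maf_required_cols, names(raw))
  if (length(missing) > 0) {
    abort(paste0("MAF: missing mandatory column(s): ", paste(missing, collapse = ", ")))
  }
  pos <- suppressWarnings(as.numeric(raw$Start_Position))
  bad <- which(is.na(pos) | pos != floor(pos))
  if (length(bad) > 0) {
    abort(paste0("MAF: non-integer Start_Position in row ", bad[1],
                 " (value '", raw$Start_Position[bad[1]], "')"))
  }
  x <- tibble(
    sample = raw$Tumor_Sample_Barcode,
    gene = raw$Hugo_Symbol,
    chrom = raw$Chromosome,
    position = as.integer(pos),
    ref = raw$Reference_Allele,
    alt = raw$Tumor_Seq_Allele2,
    variant_class = raw$Variant_Classification
  )
  validate_mutations(x)
}

#' @rdname rin_io
#' @export
validate_mutations <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("sample", "gene", "chrom", "position", "ref", "alt", "variant_class")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(paste0("mutations: missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(x$position < 1)) {
    abort("mutations: positions must be >= 1 (1-based MAF convention)")
  }
  bad <- setdiff(unique(x$variant_class), maf_variant_classes)
  if (length(bad) > 0) {
    abort(paste0("mutations: unknown variant classification(s): ",
                 paste(bad, collapse = ", ")))
  }
  as_tibble(x)
}

#' @rdname rin_io
#' @export
write_maf <- function(x, path) {
  validate_mutations(x)
  out <- tibble(
    Hugo_Symbol = x$gene,
    Tumor_Sample_Barcode = x$sample,
    Chromosome = x$chrom,
    Start_Position = x$position,
    Reference_Allele = x$ref,
    Tumor_Seq_Allele2 = x$alt,
    Variant_Classification = x$variant_class
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname rin_io
#' @export
read_annotation <- function(path, bed_coords = FALSE) {
  raw <- strict_read_tsv(path)
  need <- c("gene", "chrom", "start", "end", "strand")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(paste0("annotation: missing column(s): ", paste(missing, collapse = ", ")))
  }
  start <- suppressWarnings(as.integer(raw$start))
  end <- suppressWarnings(as.integer(raw$end))
  if (any(is.na(start)) || any(is.na(end))) abort("annotation: non-integer start/end")
  if (bed_coords) start <- start + 1L
  x <- tibble(
    gene = raw$gene, chrom = raw$chrom,
    start = start, end = end, strand = raw$strand
  )
  validate_annotation(x)
}

#' @rdname rin_io
#' @export
validate_annotation <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("gene", "chrom", "start", "end", "strand")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(paste0("annotation: missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(x$gene)) abort("annotation: duplicate gene symbols")
  bad <- which(x$end <= x$start)
  if (length(bad) > 0) {
    abort(paste0("annotation: end <= start for gene '", x$gene[bad[1]], "'"))
  }
  if (any(!x$strand %in% c("+", "-"))) abort("annotation: strand must be '+' or '-'")
  x <- mutate(as_tibble(x), length = .data$end - .data$start)
  x
}

#' @rdname rin_io
#' @export
write_annotation <- function(x, path) {
  x <- validate_annotation(x)
  readr::write_tsv(select(x, "gene", "chrom", "start", "end", "strand"), path)
  invisible(path)
}

clinical_endpoints <- c("os", "dss", "pfs")

encode_mets <- function(mets) {
  purrr::map_chr(mets, function(m) {
    if (is.null(m) || nrow(m) == 0) return("")
    paste(paste0(m$site, ":", m$time), collapse = ";")
  })
}

decode_mets <- function(s) {
  purrr::map(s, function(one) {
    if (is.na(one) || !nzchar(one)) {
      return(tibble(site = character(), time = numeric()))
    }
    parts <- strsplit(one, ";", fixed = TRUE)[[1]]
    kv <- strsplit(parts, ":", fixed = TRUE)
    bad <- lengths(kv) != 2
    if (any(bad)) abort(paste0("clinical: malformed metastasis record '", parts[bad][1], "'"))
    tibble(
      site = purrr::map_chr(kv, 1),
      time = as.numeric(purrr::map_chr(kv, 2))
    )
  })
}

#' @rdname rin_io
#' @export
read_clinical <- function(path) {
  raw <- strict_read_tsv(path)
  need <- c("patient", paste0(rep(clinical_endpoints, each = 2), c("_time", "_event")),
            "treatment", "mets")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(paste0("clinical: missing column(s): ", paste(missing, collapse = ", ")))
  }
  x <- tibble(patient = raw$patient)
  for (ep in clinical_endpoints) {
    tcol <- paste0(ep, "_time")
    ecol <- paste0(ep, "_event")
    x[[tcol]] <- suppressWarnings(as.numeric(raw[[tcol]]))
    x[[ecol]] <- suppressWarnings(as.numeric(raw[[ecol]]))
  }
  x$treatment <- raw$treatment
  x$mets <- decode_mets(raw$mets)
  validate_clinical(x)
}

#' @rdname rin_io
#' @export
validate_clinical <- function(x) {
  stopifnot(is.data.frame(x))
  if (!"patient" %in% names(x)) abort("clinical: missing 'patient' column")
  if (anyDuplicated(x$patient)) abort("clinical: duplicate patient IDs")
  for (ep in clinical_endpoints) {
    tcol <- paste0(ep, "_time")
    ecol <- paste0(ep, "_event")
    if (!tcol %in% names(x) || !ecol %in% names(x)) {
      abort(paste0("clinical: missing ", toupper(ep), " time/event columns"))
    }
    tv <- x[[tcol]]
    ev <- x[[ecol]]
    if (any(!is.na(tv) & tv < 0)) abort(paste0("clinical: negative ", tcol))
    if (any(!is.na(ev) & !ev %in% c(0, 1))) {
      abort(paste0("clinical: ", ecol, " must be 0 (censored) or 1 (event)"))
    }
  }
  if (!"treatment" %in% names(x)) abort("clinical: missing 'treatment' column")
  if (!"mets" %in% names(x)) abort("clinical: missing 'mets' column")
  for (m in x$mets) {
    if (!is.data.frame(m)) abort("clinical: 'mets' must be a list of site/time tables")
    if (nrow(m) > 0 && any(m$time < 0)) abort("clinical: negative metastasis time")
  }
  as_tibble(x)
}

#' @rdname rin_io
#' @export
write_clinical <- function(x, path) {
  x <- validate_clinical(x)
  out <- select(x, -"mets")
  out$mets <- encode_mets(x$mets)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Long table of metastasis events
#'
#' Unnests the `mets` list-column of a clinical table into one row per
#' (patient, site, time-from-diagnosis) record.
#'
#' @param clinical A clinical table (see [read_clinical()]).
#' @return Tibble with columns `patient`, `site`, `time`.
#' @export
metastasis_events <- function(clinical) {
  clinical <- validate_clinical(clinical)
  keep <- purrr::map_int(clinical$mets, nrow) > 0
  if (!any(keep)) return(tibble(patient = character(), site = character(), time = numeric()))
  tidyr::unnest(select(clinical[keep, ], "patient", "mets"), "mets")
}

#' @rdname rin_io
#' @export
read_fusions <- function(path) {
  raw <- strict_read_tsv(path)
  need <- c("sample", "gene_a", "gene_b", "chrom_a", "pos_a", "chrom_b", "pos_b",
            "microhomology", "insertion")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(paste0("fusions: missing column(s): ", paste(missing, collapse = ", ")))
  }
  x <- tibble(
    sample = raw$sample, gene_a = raw$gene_a, gene_b = raw$gene_b,
    chrom_a = raw$chrom_a,
    pos_a = suppressWarnings(as.integer(raw$pos_a)),
    chrom_b = raw$chrom_b,
    pos_b = suppressWarnings(as.integer(raw$pos_b)),
    microhomology = suppressWarnings(as.integer(raw$microhomology)),
    insertion = suppressWarnings(as.integer(raw$insertion))
  )
  validate_fusions(x)
}

#' @rdname rin_io
#' @export
validate_fusions <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("sample", "gene_a", "gene_b", "microhomology", "insertion")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(paste0("fusions: missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(is.na(x$microhomology)) || any(is.na(x$insertion))) {
    abort("fusions: microhomology/insertion must be integers")
  }
  if (any(x$microhomology < 0) || any(x$insertion < 0)) {
    abort("fusions: junction lengths must be >= 0")
  }
  both <- which(x$microhomology > 0 & x$insertion > 0)
  if (length(both) > 0) {
    abort(paste0("fusions: row ", both[1],
                 " has both microhomology and untemplated insertion > 0"))
  }
  as_tibble(x)
}

#' @rdname rin_io
#' @export
write_fusions <- function(x, path) {
  validate_fusions(x)
  readr::write_tsv(x, path)
  invisible(path)
}
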