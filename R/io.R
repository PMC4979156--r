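#' Read a gene annotation
#'
#' Reads gene records either from a GTF file (rows of feature type `"gene"`,
#' 1-based inclusive coordinates) or from a tab-separated table with header
#' `gene_id chrom start end strand` already in 0-based half-open
#' coordinates. All coordinates returned are 0-based half-open.
#'
#' @param path Path to the annotation file.
#' @param format `"gtf"` or `"tsv"`.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (one of `"+"`, `"-"`, `"*"`), one row per gene.
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines('chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tgene_id "G1";', gtf)
#' read_gene_annotation(gtf)
#' @export
read_gene_annotation <- function(path, format = c("gtf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    tnt_validation_error("gene annotation file does not exist: %s", path)
  }
  genes <- if (format == "gtf") read_genes_gtf(path) else read_genes_tsv(path)
  dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup)) {
    tnt_validation_error(
      "duplicate gene_id values in %s: %s", path,
      paste(utils::head(dup, 5), collapse = ", ")
    )
  }
  bad <- genes$start < 0 | genes$start >= genes$end
  if (any(bad)) {
    tnt_validation_error(
      "invalid gene interval (need 0 <= start < end) for: %s",
      paste(utils::head(genes$gene_id[bad], 5), collapse = ", ")
    )
  }
  genes
}

read_genes_gtf <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  out <- list()
  for (i in which(keep)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) {
      tnt_parse_error("malformed GTF line %d in %s: expected 9 tab-separated fields", i, path)
    }
    if (f[3] != "gene") next
    start1 <- suppressWarnings(as.integer(f[4]))
    end1 <- suppressWarnings(as.integer(f[5]))
    if (is.na(start1) || is.na(end1)) {
      tnt_parse_error("malformed GTF line %d in %s: non-numeric coordinates", i, path)
    }
    m <- regmatches(f[9], regexec('gene_id[ =]+"?([^";]+)"?', f[9]))[[1]]
    if (length(m) < 2) {
      tnt_parse_error("malformed GTF line %d in %s: missing gene_id attribute", i, path)
    }
    out[[length(out) + 1L]] <- data.frame(
      gene_id = m[2], chrom = f[1],
      start = start1 - 1L, end = end1, # 1-based inclusive -> 0-based half-open
      strand = if (f[7] %in% c("+", "-")) f[7] else "*",
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(
      gene_id = character(), chrom = character(), start = integer(),
      end = integer(), strand = character(), stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, out)
}

read_genes_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = NA, quote = "")
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(df))) {
    tnt_parse_error("gene TSV %s must have columns: %s", path, paste(need, collapse = " "))
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df[need]
}

# Map a RepeatMasker class/family string to one of the four TE classes,
# or NA for non-TE repeat classes (Simple_repeat, Low_complexity, ...).
te_class_from_repeat <- function(class_family) {
  prefix <- sub("/.*$", "", class_family)
  prefix <- sub("\\?$", "", prefix)
  ifelse(prefix %in% TE_CLASSES, prefix, NA_character_)
}

#' Read TE copies from a RepeatMasker `.out` file or a per-copy TSV
#'
#' RepeatMasker `.out` layout: up to 3 header lines then whitespace-separated
#' columns where column 5 is the query sequence (chromosome), columns 6 and 7
#' the 1-based inclusive begin/end, column 9 the strand (`+` or `C`),
#' column 10 the repeat family and column 11 the repeat class/family.
#' Only rows whose class prefix (before `"/"`) is one of `SINE`, `LINE`,
#' `LTR`, `DNA` are kept; other repeat classes (Simple_repeat,
#' Low_complexity, Satellite, rRNA, ...) are dropped. Alternatively a
#' pre-assembled TSV with header `chrom start end strand family te_class`
#' (0-based half-open) is accepted, e.g. the per-copy output of a fragment
#' assembler.
#'
#' @param path Path to the file.
#' @param format `"out"` (RepeatMasker) or `"tsv"` (pre-assembled dialect).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `family`, `te_class`; coordinates 0-based half-open; `te_class` one of
#'   `"DNA"`, `"LTR"`, `"LINE"`, `"SINE"`.
#' @export
read_repeatmasker_out <- function(path, format = c("out", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    tnt_validation_error("TE file does not exist: %s", path)
  }
  tes <- if (format == "out") read_rm_out(path) else read_te_tsv(path)
  if (any(tes$start < 0)) {
    tnt_validation_error("negative TE coordinates in %s", path)
  }
  if (any(tes$start >= tes$end)) {
    tnt_validation_error("TE interval with start >= end in %s", path)
  }
  tes
}

read_rm_out <- function(path) {
  lines <- readLines(path)
  # skip the standard 3-line header (column headings + blank line) and blanks
  body <- lines[!grepl("^\\s*$", lines)]
  body <- body[!grepl("^\\s*(SW|score|perc)", body)]
  empty <- data.frame(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), family = character(), te_class = character(),
    stringsAsFactors = FALSE
  )
  if (!length(body)) return(empty)
  rows <- lapply(seq_along(body), function(i) {
    f <- strsplit(trimws(body[[i]]), "\\s+")[[1]]
    if (length(f) < 11) {
      tnt_parse_error("unreadable RepeatMasker row %d in %s: %d columns, expected >= 11",
                      i, path, length(f))
    }
    begin1 <- suppressWarnings(as.integer(f[6]))
    end1 <- suppressWarnings(as.integer(f[7]))
    if (is.na(begin1) || is.na(end1)) {
      tnt_parse_error("unreadable RepeatMasker row %d in %s: non-numeric coordinates", i, path)
    }
    data.frame(
      chrom = f[5], start = begin1 - 1L, end = end1,
      strand = if (f[9] == "C") "-" else f[9],
      family = f[10], te_class = te_class_from_repeat(f[11]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[!is.na(out$te_class), , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out)) empty else out
}

read_te_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE, quote = "")
  need <- c("chrom", "start", "end", "strand", "family", "te_class")
  if (!all(need %in% names(df))) {
    tnt_parse_error("TE TSV %s must have columns: %s", path, paste(need, collapse = " "))
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  bad <- !df$te_class %in% TE_CLASSES
  if (any(bad)) {
    tnt_validation_error(
      "te_class must be one of %s; found: %s",
      paste(TE_CLASSES, collapse = "/"),
      paste(unique(df$te_class[bad]), collapse = ", ")
    )
  }
  df[need]
}

#' Read an ENCODE broadPeak (BED6+3) file
#'
#' Columns: chrom, start, end, name, score, strand, signalValue, pValue,
#' qValue. broadPeak coordinates are already 0-based half-open and are taken
#' as-is; the peak signal is the fold-enrichment `signalValue` (column 7).
#'
#' @param path Path to the broadPeak file.
#' @param mark Histone-modification name to tag the peaks with.
#' @param condition Condition label (e.g. `"normal"`, `"cancer"`).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `mark`,
#'   `condition`, `signal`.
#' @export
read_broadpeak <- function(path, mark, condition) {
  if (!file.exists(path)) {
    tnt_validation_error("broadPeak file does not exist: %s", path)
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  empty <- data.frame(
    chrom = character(), start = integer(), end = integer(),
    mark = character(), condition = character(), signal = numeric(),
    stringsAsFactors = FALSE
  )
  if (!length(lines)) return(empty)
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(f) < 7) {
      tnt_parse_error("malformed broadPeak line %d in %s: %d columns, expected >= 7",
                      i, path, length(f))
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    signal <- suppressWarnings(as.numeric(f[7]))
    if (is.na(start) || is.na(end) || is.na(signal)) {
      tnt_parse_error("malformed broadPeak line %d in %s: non-numeric fields", i, path)
    }
    data.frame(chrom = f[1], start = start, end = end,
               mark = mark, condition = condition, signal = signal,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$signal < 0)) {
    tnt_validation_error("negative signalValue in %s", path)
  }
  if (any(out$start < 0 | out$start >= out$end)) {
    tnt_validation_error("invalid peak interval (need 0 <= start < end) in %s", path)
  }
  out
}

#' Read a differential-expression results table
#'
#' TSV with header `gene_id log2fc padj`; `"NA"` marks a missing adjusted
#' p-value (such genes are never counted as significant).
#'
#' @param path Path to the TSV.
#' @return A `data.frame` with columns `gene_id`, `log2fc`, `padj`.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) {
    tnt_validation_error("DE table does not exist: %s", path)
  }
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = "NA", quote = "")
  need <- c("gene_id", "log2fc", "padj")
  if (!all(need %in% names(df))) {
    tnt_parse_error("DE table %s must have columns: %s", path, paste(need, collapse = " "))
  }
  df$log2fc <- as.numeric(df$log2fc)
  df$padj <- as.numeric(df$padj)
  bad <- !is.na(df$padj) & (df$padj < 0 | df$padj > 1)
  if (any(bad)) {
    tnt_validation_error(
      "padj outside [0, 1] for: %s",
      paste(utils::head(df$gene_id[bad], 5), collapse = ", ")
    )
  }
  df[need]
}

#' Write a per-gene table as TSV
#'
#' Tab-separated with a header line; `NA` for missing values. Reading the
#' file back (e.g. with [read_de_table()] for DE tables) reproduces the
#' field values.
#'
#' @param records A `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a UCSC-style chrom.sizes file
#'
#' Two tab-separated columns (no header): chromosome name and length in bp.
#'
#' @param path Path to the file.
#' @return A named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) {
    tnt_validation_error("chrom sizes file does not exist: %s", path)
  }
  df <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2) {
    tnt_parse_error("chrom sizes file %s must have 2 tab-separated columns", path)
  }
  setNames(as.integer(df[[2]]), df[[1]])
}

#' Warn when gene and TE annotations share no chromosome names
#'
#' Chromosome matching in the package is exact string equality (no "chr"
#' aliasing); this check catches annotation sets that use different naming
#' schemes.
#'
#' @param genes Gene table from [read_gene_annotation()].
#' @param tes TE table from [read_repeatmasker_out()].
#' @return `TRUE` (invisibly) if the chromosome name sets intersect.
#' @export
check_chromosome_names <- function(genes, tes) {
  ok <- length(intersect(unique(genes$chrom), unique(tes$chrom))) > 0
  if (!ok) {
    warning("gene and TE chromosome name sets are disjoint; ",
            "chromosome matching is exact (no 'chr' aliasing)",
            call. = FALSE)
  }
  invisible(ok)
}
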