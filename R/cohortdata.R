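# Data containers and file I/O for counts, clinical metadata and Ct tables.
#
# Counts travel as a gene x sample integer matrix (genes in rows, matching
# featureCounts-style exports); metadata and Ct tables are plain data frames
# with validated columns. All readers log every normalised or rejected record
# with its line number rather than silently dropping rows.

GROUP_LEVELS   <- c("healthy", "tumour", "post_therapy", "high_risk")
SEX_LEVELS     <- c("male", "female")
SMOKING_LEVELS <- c("none", "light", "heavy")
SWAB_LEVELS    <- c("lesion", "contralateral_normal")
P16_LEVELS     <- c("pos", "neg")

# Clinical sheets are inconsistently cased; accept synonyms, log the mapping.
GROUP_SYNONYMS <- c(
  "healthy" = "healthy", "tumour" = "tumour", "tumor" = "tumour",
  "post_therapy" = "post_therapy", "post-therapy" = "post_therapy",
  "posttherapy" = "post_therapy", "high_risk" = "high_risk",
  "high-risk" = "high_risk", "high risk" = "high_risk"
)

#' Construct a validated count matrix
#'
#' Bundles an integer gene x sample RNA-seq count matrix with an optional
#' technical-replicate map. Genes are rows, samples are columns.
#'
#' @param counts Numeric matrix of non-negative integers with unique rownames
#'   (gene ids) and colnames (sample ids).
#' @param replicate_of Optional named character vector mapping a replicate
#'   sample id to the biological (parent) sample id it re-measures.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `replicate_of`.
#' @examples
#' m <- matrix(0:3, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' count_matrix(m)
#' @export
count_matrix <- function(counts, replicate_of = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop_fmt("'counts' must be a numeric matrix")
  }
  gene_ids <- rownames(counts)
  sample_ids <- colnames(counts)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop_fmt("'counts' must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(gene_ids)) stop_fmt("duplicate gene ids in count matrix")
  if (anyDuplicated(sample_ids)) stop_fmt("duplicate sample ids in count matrix")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop_fmt("counts must be non-negative integers without missing values")
  }
  storage.mode(counts) <- "integer"
  if (!is.null(replicate_of)) {
    if (is.null(names(replicate_of)) || anyDuplicated(names(replicate_of))) {
      stop_fmt("'replicate_of' must be uniquely named (replicate -> parent)")
    }
    bad <- setdiff(c(names(replicate_of), unname(replicate_of)), sample_ids)
    if (length(bad)) {
      stop_fmt("replicate map refers to unknown sample(s): %s",
               paste(bad, collapse = ", "))
    }
  }
  structure(list(counts = counts, replicate_of = replicate_of),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$replicate_of)) {
    cat(sprintf("  technical replicates: %d mapped\n", length(x$replicate_of)))
  }
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a gene x sample count matrix from TSV
#'
#' Expects a tab-separated file whose first column (`gene_id`) holds gene
#' identifiers and whose remaining header fields are sample ids. Entries must
#' be non-negative integers.
#'
#' @param path Path to the TSV file.
#' @param replicate_of Optional replicate map, as in [count_matrix()].
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, replicate_of = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop_fmt("counts file '%s' is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (length(header) < 2L) stop_fmt("counts file needs a gene column and >= 1 sample")
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids)) stop_fmt("duplicated sample id in counts header")
  width <- length(header)
  body <- fields[-1]
  ragged <- which(lengths(body) != width)
  if (length(ragged)) {
    stop_fmt("ragged row(s) in counts file at line(s) %s",
             paste(ragged + 1L, collapse = ", "))
  }
  gene_ids <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(gene_ids)) stop_fmt("duplicated gene id in counts file")
  m <- suppressWarnings(
    do.call(rbind, lapply(body, function(f) as.numeric(f[-1])))
  )
  dimnames(m) <- list(gene_ids, sample_ids)
  if (anyNA(m) || any(m < 0) || any(m != round(m))) {
    stop_fmt("counts file contains non-integer or negative entries")
  }
  count_matrix(m, replicate_of = replicate_of)
}

#' Write a count matrix to TSV
#'
#' Inverse of [read_counts()]; the round trip is exact.
#'
#' @param x A [count_matrix()].
#' @param path Output path.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

normalise_group <- function(g, line = NULL) {
  key <- tolower(trimws(g))
  out <- unname(GROUP_SYNONYMS[key])
  bad <- which(is.na(out) & !is.na(g) & nzchar(key))
  if (length(bad)) {
    where <- if (is.null(line)) bad else line[bad]
    stop_fmt("unknown group label(s) %s at row(s) %s",
             paste(sQuote(unique(g[bad])), collapse = ", "),
             paste(where, collapse = ", "))
  }
  changed <- which(!is.na(g) & out != g)
  if (length(changed)) {
    where <- if (is.null(line)) changed else line[changed]
    message(sprintf("normalised group label at row(s) %s: %s",
                    paste(where, collapse = ", "),
                    paste(unique(sprintf("%s -> %s", g[changed], out[changed])),
                          collapse = ", ")))
  }
  out
}

normalise_enum <- function(x, levels, col, line) {
  key <- tolower(trimws(x))
  key[!nzchar(key) | key %in% c("na", "n/a", "-")] <- NA_character_
  bad <- which(!is.na(key) & !key %in% levels)
  if (length(bad)) {
    stop_fmt("invalid %s value(s) %s at row(s) %s", col,
             paste(sQuote(unique(x[bad])), collapse = ", "),
             paste(line[bad], collapse = ", "))
  }
  key
}

#' Construct a validated sample metadata table
#'
#' @param df Data frame with at least `sample_id`, `group` and `sex` columns;
#'   optional columns (`subject_id`, `smoking`, `swab_site`, `p16_status`,
#'   staging fields) are validated when present and otherwise filled with NA.
#' @return A data frame of class `sample_table`.
#' @export
sample_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_fmt("metadata lacks column(s): %s", paste(miss, collapse = ", "))
  line <- seq_len(nrow(df)) + 1L  # header is line 1 in the file form
  if (anyNA(df$sample_id) || any(!nzchar(df$sample_id))) {
    stop_fmt("missing sample_id at row(s) %s",
             paste(line[is.na(df$sample_id) | !nzchar(df$sample_id)], collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop_fmt("duplicate sample_id in metadata")
  df$group <- normalise_group(df$group, line)
  df$sex <- normalise_enum(df$sex, SEX_LEVELS, "sex", line)
  if (anyNA(df$group)) stop_fmt("missing group in metadata")
  if (anyNA(df$sex)) stop_fmt("missing sex in metadata")
  for (col in c("subject_id", "smoking", "swab_site", "p16_status",
                "t_stage", "n_stage", "m_stage", "grading", "localisation")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  df$smoking <- normalise_enum(df$smoking, SMOKING_LEVELS, "smoking", line)
  df$swab_site <- normalise_enum(df$swab_site, SWAB_LEVELS, "swab_site", line)
  df$p16_status <- normalise_enum(df$p16_status, P16_LEVELS, "p16_status", line)
  offenders <- df$group == "healthy" & !is.na(df$swab_site) & df$swab_site == "lesion"
  if (any(offenders)) {
    stop_fmt("healthy sample(s) cannot have swab_site = lesion: %s",
             paste(df$sample_id[offenders], collapse = ", "))
  }
  df$subject_id[is.na(df$subject_id)] <- df$sample_id[is.na(df$subject_id)]
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Read sample metadata from CSV
#'
#' Group labels are matched case-insensitively with common synonyms
#' (`"Tumor"`, `"post-therapy"`, `"high risk"`); every normalisation is
#' reported via `message()` with its row number.
#'
#' @param path Path to a CSV file with header `sample_id,group,sex,...`.
#' @return A [sample_table()].
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  sample_table(df)
}

#' Write sample metadata to CSV
#' @param x A [sample_table()].
#' @param path Output path.
#' @export
write_metadata <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE,
                   na = "NA")
  invisible(path)
}

#' Construct a validated long-format Ct table
#'
#' @param df Data frame with columns `sample_id`, `gene`, `replicate`
#'   (integer >= 1) and `ct` (cycle threshold in \[0, 45\], NA allowed —
#'   a failed well is explicit, never encoded as a sentinel like 40).
#' @return A data frame of class `ct_table`.
#' @export
ct_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene", "replicate", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_fmt("Ct table lacks column(s): %s", paste(miss, collapse = ", "))
  df$replicate <- as.integer(df$replicate)
  if (anyNA(df$replicate) || any(df$replicate < 1L)) {
    stop_fmt("replicate indices must be integers >= 1")
  }
  key <- paste(df$sample_id, df$gene, df$replicate, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop_fmt("duplicate (sample, gene, replicate) row(s) at line(s) %s",
             paste(dup + 1L, collapse = ", "))
  }
  df$ct <- as.numeric(df$ct)
  bad <- which(!is.na(df$ct) & (df$ct < 0 | df$ct > 45))
  if (length(bad)) {
    stop_fmt("Ct value(s) outside [0, 45] at line(s) %s",
             paste(bad + 1L, collapse = ", "))
  }
  class(df) <- c("ct_table", "data.frame")
  df
}

#' Read a long-format Ct table from CSV
#'
#' Expects header `sample_id,gene,replicate,ct`; empty or "NA" Ct fields are
#' missing values.
#'
#' @param path Path to the CSV file.
#' @return A [ct_table()].
#' @export
read_ct <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  ct_table(df)
}

#' Write a Ct table to CSV
#' @param x A [ct_table()].
#' @param path Output path.
#' @export
write_ct <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE,
                   na = "NA")
  invisible(path)
}

#' Write a generic result table to TSV
#'
#' Column order and row order are preserved; [read_result()] restores the
#' table losslessly for character and numeric columns.
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_result <- function(x, path) {
  if (anyDuplicated(names(x))) stop_fmt("result table has duplicated column names")
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a result table written by [write_result()]
#' @param path Path to the TSV file.
#' @return A data frame.
#' @export
read_result <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
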