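#' Read chromatin loops from BEDPE
#'
#' BEDPE with at least 6 columns (`chrom1 start1 end1 chrom2 start2 end2`).
#' A header line starting with `#` may name extra columns; recognised names
#' (`observed`, `expected_local`, `p_value`, `q_value`, `sample_id`) are
#' attached to the returned loop table. Anchors are re-ordered so that
#' anchor1 lies upstream of anchor2.
#'
#' @param path Path to a BEDPE file.
#' @param trans Either "error" (reject inter-chromosomal pairs) or "skip".
#' @return A loop tibble (`chrom1,start1,end1,chrom2,start2,end2`, plus any
#'   recognised extra columns).
#' @export
read_bedpe <- function(path, trans = c("error", "skip")) {
  trans <- match.arg(trans)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  extra <- character()
  if (length(hdr)) {
    fields <- strsplit(sub("^#", "", hdr[1]), "\t")[[1]]
    if (length(fields) > 6) extra <- fields[-(1:6)]
  }
  if (!length(body)) return(empty_loops())
  parts <- strsplit(body, "\t")
  ncol1 <- length(parts[[1]])
  bad <- which(vapply(parts, length, 1L) < 6L)
  if (length(bad)) stop("malformed BEDPE line ", bad[1] + length(hdr))
  m <- do.call(rbind, lapply(parts, function(p) p[seq_len(ncol1)]))
  loops <- tibble::tibble(
    chrom1 = m[, 1], start1 = as.numeric(m[, 2]), end1 = as.numeric(m[, 3]),
    chrom2 = m[, 4], start2 = as.numeric(m[, 5]), end2 = as.numeric(m[, 6]))
  if (anyNA(loops$start1) || anyNA(loops$end1) ||
      anyNA(loops$start2) || anyNA(loops$end2)) {
    stop("malformed BEDPE line ",
         which(is.na(loops$start1) | is.na(loops$end1) |
               is.na(loops$start2) | is.na(loops$end2))[1] + length(hdr))
  }
  if (length(extra) && ncol1 >= 6 + length(extra)) {
    for (k in seq_along(extra)) {
      nm <- extra[k]
      if (nm %in% c("observed", "expected_local", "p_value", "q_value")) {
        loops[[nm]] <- suppressWarnings(as.numeric(m[, 6 + k]))
      } else if (nm == "sample_id") {
        loops[[nm]] <- m[, 6 + k]
      }
    }
  }
  is_trans <- loops$chrom1 != loops$chrom2
  if (any(is_trans)) {
    if (trans == "error") stop("trans pair at BEDPE line ",
                               which(is_trans)[1] + length(hdr))
    loops <- loops[!is_trans, , drop = FALSE]
  }
  order_anchors(loops)
}

empty_loops <- function() {
  tibble::tibble(chrom1 = character(), start1 = numeric(), end1 = numeric(),
                 chrom2 = character(), start2 = numeric(), end2 = numeric())
}

# Enforce the anchor1-upstream invariant on a loop table.
order_anchors <- function(loops) {
  swap <- loops$start1 > loops$start2
  if (any(swap)) {
    s1 <- loops$start1[swap]; e1 <- loops$end1[swap]
    loops$start1[swap] <- loops$start2[swap]
    loops$end1[swap] <- loops$end2[swap]
    loops$start2[swap] <- s1
    loops$end2[swap] <- e1
  }
  loops
}

#' Write chromatin loops to BEDPE
#'
#' Extra columns present in `loops` among `observed`, `expected_local`,
#' `p_value`, `q_value`, `sample_id` are written after the six coordinate
#' columns and named in a `#` header line.
#'
#' @param loops A loop tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(loops, path) {
  extras <- intersect(c("observed", "expected_local", "p_value", "q_value",
                        "sample_id"), names(loops))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#chrom1", "start1", "end1", "chrom2", "start2", "end2",
                     extras), collapse = "\t"), con)
  if (nrow(loops)) {
    df <- data.frame(loops$chrom1, format_bp(loops$start1),
                     format_bp(loops$end1), loops$chrom2,
                     format_bp(loops$start2), format_bp(loops$end2))
    for (nm in extras) {
      df[[nm]] <- if (is.numeric(loops[[nm]])) {
        format(loops[[nm]], digits = 15, trim = TRUE)
      } else loops[[nm]]
    }
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read genomic intervals from BED or bedGraph
#'
#' BED3+ intervals; a numeric fourth column (bedGraph) is attached as
#' `value`. Lines starting with `#`, `track` or `browser` are skipped.
#'
#' @param path Path to a BED/bedGraph file.
#' @param genome Optional `ld_genome` for validation.
#' @return An interval tibble (`chrom`, `start`, `end`, optionally `value`).
#' @export
read_intervals <- function(path, genome = NULL) {
  lines <- readLines(path)
  body <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(body)) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric()))
  }
  parts <- strsplit(body, "\t")
  bad <- which(vapply(parts, length, 1L) < 3L)
  if (length(bad)) stop("malformed BED line ", bad[1])
  out <- tibble::tibble(
    chrom = vapply(parts, `[[`, "", 1L),
    start = as.numeric(vapply(parts, `[[`, "", 2L)),
    end = as.numeric(vapply(parts, `[[`, "", 3L)))
  if (all(vapply(parts, length, 1L) >= 4L)) {
    val <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 4L)))
    if (!anyNA(val)) out$value <- val
  }
  validate_intervals(out, genome)
}

#' Write genomic intervals as BED/bedGraph
#'
#' @param intervals Interval tibble; a `value` column makes it bedGraph.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  df <- data.frame(intervals$chrom, format_bp(intervals$start),
                   format_bp(intervals$end))
  if ("value" %in% names(intervals)) {
    df$value <- format(intervals$value, digits = 15, trim = TRUE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an expression table (TSV, FPKM) and sample group labels
#'
#' The expression TSV has a header row: first column `gene_id`, one column
#' per sample of non-negative FPKM values. The labels file is two TAB
#' separated columns `sample<TAB>group` without header.
#'
#' @param expr_path Path to the expression TSV.
#' @param labels_path Path to the sample/group labels file.
#' @return A list with `expr` (tibble, `gene_id` + one column per sample)
#'   and `labels` (tibble `sample`, `group`).
#' @export
read_expression <- function(expr_path, labels_path) {
  expr <- readr::read_tsv(expr_path, show_col_types = FALSE)
  names(expr)[1] <- "gene_id"
  if (anyDuplicated(expr$gene_id)) stop("duplicate gene ids")
  vals <- as.matrix(expr[, -1])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("expression values must be finite and >= 0")
  }
  labels <- utils::read.table(labels_path, sep = "\t", header = FALSE,
                              col.names = c("sample", "group"),
                              colClasses = "character")
  missing <- setdiff(names(expr)[-1], labels$sample)
  if (length(missing)) stop("samples without group label: ",
                            paste(missing, collapse = ", "))
  list(expr = expr, labels = tibble::as_tibble(labels))
}

#' Write an expression table and its labels
#'
#' @param expr Expression tibble (`gene_id` + sample columns).
#' @param labels Labels tibble (`sample`, `group`).
#' @param expr_path,labels_path Output paths.
#' @return `expr_path`, invisibly.
#' @export
write_expression <- function(expr, labels, expr_path, labels_path) {
  readr::write_tsv(expr, expr_path)
  utils::write.table(as.data.frame(labels), labels_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(expr_path)
}
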