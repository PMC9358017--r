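# FASTA and table I/O. Parsing is delegated to Biostrings; sequences are
# normalised to upper-case DNA on the way in (RNA input accepted).

#' Read a (multi-)FASTA file
#'
#' Record ids are the first whitespace-delimited token of each header.
#' Sequences are upper-cased and U is mapped to T; other characters (gaps,
#' ambiguity codes) are left as-is.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("FASTA file '%s' does not exist", path), call. = FALSE)
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    stop(sprintf("malformed FASTA file '%s': %s",
                                 path, conditionMessage(e)), call. = FALSE)
                  })
  if (length(set) == 0L) {
    stop(sprintf("FASTA file '%s' contains no records", path), call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate record id '%s' in '%s'",
                 ids[duplicated(ids)][1], path), call. = FALSE)
  }
  stats::setNames(vapply(as.character(set), .normalize_sequence,
                         character(1), USE.NAMES = FALSE), ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param alphabet render as DNA (default) or RNA (T written as U).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, alphabet = c("dna", "rna")) {
  alphabet <- match.arg(alphabet)
  if (is.null(names(seqs))) stop("sequences must be named", call. = FALSE)
  x <- vapply(seqs, .normalize_sequence, character(1))
  if (alphabet == "rna") x <- chartr("T", "U", x)
  Biostrings::writeXStringSet(Biostrings::BStringSet(x), filepath = path)
  invisible(path)
}

.format_num <- function(x, precision) {
  if (precision == "display") sprintf("%.3f", x) else format(x, digits = 15)
}

#' Write a result table to TSV or markdown
#'
#' Numeric columns are rendered to 3 decimals by default (full precision
#' with `precision = "full"`); column order is preserved; output is
#' deterministic byte-for-byte for identical input.
#'
#' @param table a data.frame (e.g. from [site_table()] or
#'   [codon_fs_summary()]).
#' @param path output path.
#' @param format `"tsv"` (default) or `"markdown"`.
#' @param precision `"display"` (3 decimals) or `"full"`.
#' @param alphabet render codon columns as DNA (default) or RNA.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path, format = c("tsv", "markdown"),
                        precision = c("display", "full"),
                        alphabet = c("dna", "rna")) {
  format <- match.arg(format)
  precision <- match.arg(precision)
  alphabet <- match.arg(alphabet)
  out <- as.data.frame(table)
  for (cl in names(out)) {
    if (is.double(out[[cl]])) out[[cl]] <- .format_num(out[[cl]], precision)
    if (alphabet == "rna" && cl %in% c("codon", "ref_codon", "alt_codon",
                                       "target")) {
      out[[cl]] <- chartr("T", "U", out[[cl]])
    }
  }
  if (format == "tsv") {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    header <- paste0("| ", paste(names(out), collapse = " | "), " |")
    rule <- paste0("|", paste(rep("---", ncol(out)), collapse = "|"), "|")
    body <- apply(out, 1L, function(r) paste0("| ", paste(r, collapse = " | "),
                                              " |"))
    writeLines(c(header, rule, body), path, useBytes = TRUE)
  }
  invisible(path)
}
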