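# SNP extraction from multi-strain codon alignments and the fS
# (observed/expected synonymous polymorphism) statistic.

#' Extract SNPs from a codon-aligned multi-strain alignment
#'
#' Compares every non-reference record to the reference column by column and
#' emits one record per (column, distinct non-reference allele), with the
#' number of strains carrying the allele in `allele_count`. Classification
#' (synonymous / missense / nonsense, transition / transversion) is always
#' relative to the reference codon at that column. Columns whose reference
#' codon contains a non-ACGT character or is a stop codon are skipped;
#' non-ACGT characters in a strain exclude only that strain's observation at
#' that column.
#'
#' @inheritParams sense_codons
#' @param alignment named character vector (or `XStringSet`) of equal-length
#'   in-frame sequences, one per strain.
#' @param reference_id name of the reference record.
#' @param gene_id optional gene label copied into the output.
#' @return data.frame with columns `gene_id`, `codon_index`,
#'   `codon_position` (1-3), `ref_base`, `alt_base`, `ref_codon`,
#'   `alt_codon`, `effect`, `is_transition`, `allele_count`; one row per
#'   (column, allele), ordered by position then allele.
#' @examples
#' aln <- c(reference = "TTTAAA", s1 = "TTCAAA", s2 = "TTCAAA")
#' extract_snps(aln, "reference")  # one synonymous transition, count 2
#' @export
extract_snps <- function(alignment, reference_id = "reference",
                         gene_id = NA_character_, code = "standard") {
  dat <- .codon_data(code)
  if (methods::is(alignment, "XStringSet")) {
    alignment <- stats::setNames(as.character(alignment), names(alignment))
  }
  if (is.null(names(alignment)) || any(!nzchar(names(alignment)))) {
    stop("alignment records must be named", call. = FALSE)
  }
  if (anyDuplicated(names(alignment))) {
    stop(sprintf("duplicate record id '%s' in alignment",
                 names(alignment)[duplicated(names(alignment))][1]),
         call. = FALSE)
  }
  if (!reference_id %in% names(alignment)) {
    stop(sprintf("reference id '%s' not found in alignment", reference_id),
         call. = FALSE)
  }
  seqs <- vapply(alignment, .normalize_sequence, character(1))
  len <- unique(nchar(seqs))
  if (length(len) != 1L) {
    stop("alignment records have unequal lengths", call. = FALSE)
  }
  if (len %% 3L != 0L) {
    stop("alignment length is not a multiple of 3", call. = FALSE)
  }

  empty <- data.frame(gene_id = character(0), codon_index = integer(0),
                      codon_position = integer(0), ref_base = character(0),
                      alt_base = character(0), ref_codon = character(0),
                      alt_codon = character(0), effect = character(0),
                      is_transition = logical(0), allele_count = integer(0),
                      stringsAsFactors = FALSE)
  if (len == 0L) return(empty)

  ref <- seqs[[reference_id]]
  refc <- strsplit(ref, "", fixed = TRUE)[[1]]
  rcod <- .split_codons(ref)
  codon_ok <- grepl("^[ACGT]{3}$", rcod) & !(rcod %in% dat$stops)
  pos_ok <- rep(codon_ok, each = 3L)

  pos_all <- integer(0)
  alt_all <- character(0)
  for (id in setdiff(names(seqs), reference_id)) {
    sc <- strsplit(seqs[[id]], "", fixed = TRUE)[[1]]
    d <- which(sc != refc & pos_ok & sc %in% .BASES)
    pos_all <- c(pos_all, d)
    alt_all <- c(alt_all, sc[d])
  }
  if (length(pos_all) == 0L) return(empty)

  key <- paste(pos_all, alt_all)
  cnt <- table(key)
  first <- !duplicated(key)
  pos <- pos_all[first]
  alt <- alt_all[first]
  n <- as.integer(cnt[paste(pos, alt)])
  o <- order(pos, alt)
  pos <- pos[o]
  alt <- alt[o]
  n <- n[o]

  ci <- (pos - 1L) %/% 3L + 1L
  cp <- (pos - 1L) %% 3L + 1L
  ref_codon <- rcod[ci]
  alt_codon <- ref_codon
  substr(alt_codon, cp, cp) <- alt
  aa_ref <- dat$aa[ref_codon]
  aa_alt <- dat$aa[alt_codon]
  effect <- ifelse(aa_alt == "*", "nonsense",
            ifelse(aa_alt == aa_ref, "synonymous", "missense"))
  data.frame(gene_id = gene_id, codon_index = ci, codon_position = cp,
             ref_base = refc[pos], alt_base = alt, ref_codon = ref_codon,
             alt_codon = alt_codon, effect = unname(effect),
             is_transition = .is_transition(refc[pos], alt),
             allele_count = n, stringsAsFactors = FALSE)
}

#' Per-codon observed/expected polymorphism summary (fS)
#'
#' Aggregates SNP records by reference codon identity (over all occurrences,
#' and over genes if records from several alignments are combined) and
#' computes, per codon: observed synonymous changes `So`, observed
#' non-synonymous changes `NSo` (missense + nonsense), the equal-rate
#' expectations `Se = s9/9 * (So + NSo)` and `NSe = (9 - s9)/9 * (So + NSo)`
#' where `s9` is the codon's number of synonymous single-base neighbors, and
#' `fS = So / Se`. `fS` is 0 for codons with no observed changes and `NA`
#' for ATG and TGG (`s9 = 0`, no synonymous change possible), leaving the 59
#' codons usually compared.
#'
#' @inheritParams sense_codons
#' @param snps data.frame from [extract_snps()] (rows from several genes may
#'   be concatenated with `rbind`).
#' @param count `"alleles"` (default): each distinct (column, allele)
#'   polymorphism counts once; `"strains"`: observations are weighted by
#'   `allele_count`.
#' @return data.frame of class `fs_table`, one row per sense codon:
#'   `codon`, `amino_acid`, `degeneracy_class`, `So`, `NSo`, `Se`, `NSe`,
#'   `fS`.
#' @export
codon_fs_summary <- function(snps, count = c("alleles", "strains"),
                             code = "standard") {
  count <- match.arg(count)
  dat <- .codon_data(code)
  w <- if (count == "strains") snps$allele_count else rep(1L, nrow(snps))
  sense <- dat$sense
  So <- NSo <- stats::setNames(numeric(length(sense)), sense)
  if (nrow(snps) > 0L) {
    syn <- snps$effect == "synonymous"
    s_sum <- tapply(w[syn], snps$ref_codon[syn], sum)
    n_sum <- tapply(w[!syn], snps$ref_codon[!syn], sum)
    So[names(s_sum)] <- s_sum
    NSo[names(n_sum)] <- n_sum
  }
  prof <- dat$profile[sense, ]
  s9 <- prof$Sti + prof$Stv
  total <- So + NSo
  Se <- s9 / 9 * total
  NSe <- (9 - s9) / 9 * total
  fS <- ifelse(s9 == 0, NA_real_,
        ifelse(total == 0, 0, unname(So / total) * (9 / s9)))
  out <- data.frame(codon = sense, amino_acid = prof$amino_acid,
                    degeneracy_class = unname(dat$degeneracy[sense]),
                    So = unname(So), NSo = unname(NSo),
                    Se = unname(Se), NSe = unname(NSe), fS = unname(fS),
                    stringsAsFactors = FALSE)
  attr(out, "count") <- count
  class(out) <- c("fs_table", "data.frame")
  out
}

#' Compare fS values between degeneracy classes
#'
#' Summarises fS per degeneracy class and performs a two-sided Wilcoxon
#' rank-sum (Mann-Whitney U) comparison between two classes, by default
#' twofold vs fourfold. Codons with no observed changes (or undefined fS)
#' carry no information and are dropped.
#'
#' @param fs_table an [codon_fs_summary()] table.
#' @param classes length-2 character vector: the two classes compared.
#' @param exact use the exact rank-sum distribution (sensible for very small
#'   classes only); default `FALSE` uses the tie-corrected normal
#'   approximation.
#' @return list with `classes`, `class_summary` (data.frame: class, n, mean,
#'   median, min, max), `U` (statistic for the first class) and `p_value`
#'   (two-sided); `U` and `p_value` are `NA` when either class has fewer
#'   than 2 usable codons.
#' @export
fs_class_comparison <- function(fs_table, classes = c("twofold", "fourfold"),
                                exact = FALSE) {
  stopifnot(length(classes) == 2L)
  usable <- !is.na(fs_table$fS) & (fs_table$So + fs_table$NSo) > 0
  vals <- function(cl) fs_table$fS[usable & fs_table$degeneracy_class == cl]
  all_classes <- intersect(
    c("twofold", "threefold", "fourfold", "sixfold_family", "sixfold_split",
      "onefold"),
    unique(fs_table$degeneracy_class))
  class_summary <- do.call(rbind, lapply(all_classes, function(cl) {
    v <- vals(cl)
    data.frame(class = cl, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               median = if (length(v)) stats::median(v) else NA_real_,
               min = if (length(v)) min(v) else NA_real_,
               max = if (length(v)) max(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  x <- vals(classes[1])
  y <- vals(classes[2])
  if (length(x) < 2L || length(y) < 2L) {
    return(list(classes = classes, class_summary = class_summary,
                U = NA_real_, p_value = NA_real_,
                undefined = "fewer_than_2_codons_in_a_class"))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = FALSE))
  list(classes = classes, class_summary = class_summary,
       U = unname(wt$statistic), p_value = wt$p.value, undefined = NULL)
}
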