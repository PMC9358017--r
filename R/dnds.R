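# Pairwise gene dN/dS from single-substitution codon differences, under the
# old (equal-rate) or modified (kappa-weighted, nonsense-corrected) site
# model, plus gene-level composition covariates and the old-vs-modified
# method comparison.

#' Summed site values of a coding sequence
#'
#' Sums per-codon S and NS site values over the codons of one in-frame CDS.
#' A terminal stop codon is stripped; codons containing non-ACGT characters
#' (ambiguity codes, gaps) are skipped and counted. Internal stop codons are
#' an error by default since inputs are expected to be intact CDS.
#'
#' @inheritParams codon_sites
#' @param cds coding sequence (single character string, DNA or RNA; length a
#'   multiple of 3).
#' @param skip_internal_stop if `TRUE`, internal stop codons are skipped
#'   (and counted in `n_codons_skipped`) instead of raising an error.
#' @param id optional record id used in error messages.
#' @return list with `id`, `method`, `kappa`, `S_total`, `N_total`,
#'   `n_codons_counted`, `n_codons_skipped`.
#' @examples
#' gene_sites("ATGTGG", method = "modified", kappa = 4)  # N_total = 4.667
#' @export
gene_sites <- function(cds, method = c("modified", "old"), kappa = 4,
                       code = "standard", skip_internal_stop = FALSE,
                       id = NULL) {
  method <- match.arg(method)
  dat <- .codon_data(code)
  x <- .normalize_sequence(cds)
  cod <- .split_codons(x, id)
  if (length(cod) > 0L && cod[length(cod)] %in% dat$stops) {
    cod <- cod[-length(cod)]
  }
  ok <- grepl("^[ACGT]{3}$", cod)
  skipped <- sum(!ok)
  cod <- cod[ok]
  is_stop <- cod %in% dat$stops
  if (any(is_stop)) {
    if (!skip_internal_stop) {
      stop(sprintf("internal stop codon %s at codon %d%s",
                   cod[is_stop][1], which(is_stop)[1],
                   if (is.null(id)) "" else sprintf(" of '%s'", id)),
           call. = FALSE)
    }
    skipped <- skipped + sum(is_stop)
    cod <- cod[!is_stop]
  }
  if (length(cod) == 0L) {
    return(list(id = id, method = method,
                kappa = if (method == "modified") .check_kappa(kappa) else NA_real_,
                S_total = 0, N_total = 0,
                n_codons_counted = 0L, n_codons_skipped = skipped))
  }
  counts <- table(cod)
  st <- codon_sites(names(counts), method, kappa, code)
  list(id = id, method = method, kappa = st$kappa[1],
       S_total = sum(st$S * as.vector(counts)),
       N_total = sum(st$NS * as.vector(counts)),
       n_codons_counted = length(cod), n_codons_skipped = skipped)
}

#' Count synonymous and non-synonymous codon differences between two CDS
#'
#' Codons are compared positionally. Pairs differing at exactly one position
#' are classified synonymous (`Sd`) or non-synonymous (`Nd`) by translation;
#' pairs differing at two or three positions are excluded from the counts
#' (no substitution-pathway averaging) and reported in `n_multi`. Pairs
#' where either codon is a stop or contains a non-ACGT character are
#' excluded entirely (`n_excluded`).
#'
#' @inheritParams sense_codons
#' @param cds_a,cds_b equal-length in-frame coding sequences.
#' @return list with `Sd`, `Nd`, `n_single`, `n_multi`, `n_identical`,
#'   `n_excluded`.
#' @examples
#' count_codon_differences("TTT", "TTC")  # Sd = 1
#' count_codon_differences("ATG", "ACG")  # Nd = 1
#' @export
count_codon_differences <- function(cds_a, cds_b, code = "standard") {
  dat <- .codon_data(code)
  a <- .normalize_sequence(cds_a)
  b <- .normalize_sequence(cds_b)
  if (nchar(a) != nchar(b)) {
    stop(sprintf("sequences have unequal lengths (%d vs %d); aligned equal-length CDS required",
                 nchar(a), nchar(b)), call. = FALSE)
  }
  ca <- .split_codons(a, "cds_a")
  cb <- .split_codons(b, "cds_b")
  ok <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb) &
    !(ca %in% dat$stops) & !(cb %in% dat$stops)
  n_excluded <- sum(!ok)
  ca <- ca[ok]
  cb <- cb[ok]
  nd <- (substr(ca, 1, 1) != substr(cb, 1, 1)) +
    (substr(ca, 2, 2) != substr(cb, 2, 2)) +
    (substr(ca, 3, 3) != substr(cb, 3, 3))
  single <- nd == 1L
  syn <- dat$aa[ca[single]] == dat$aa[cb[single]]
  list(Sd = sum(syn), Nd = sum(!syn),
       n_single = sum(single), n_multi = sum(nd >= 2L),
       n_identical = sum(nd == 0L), n_excluded = n_excluded)
}

.jc_correct <- function(p) {
  ifelse(p >= 0.75, NaN, -0.75 * log(1 - 4 * p / 3))
}

#' Pairwise gene dN/dS
#'
#' Counts single-substitution codon differences between two equal-length
#' CDS, normalises by S and NS sites (averaged over the two sequences by
#' default) and returns pN/pS. No multiple-hit correction is applied by
#' default; `jc_correction = TRUE` applies the Jukes-Cantor transform
#' -3/4 log(1 - 4p/3) to both proportions first.
#'
#' @inheritParams count_codon_differences
#' @inheritParams codon_sites
#' @param sites `"mean"` (average sites of the two sequences, default) or
#'   `"first"` (sites of `cds_a` only).
#' @param jc_correction apply the Jukes-Cantor distance transform to pS and
#'   pN before forming the ratio.
#' @param ids optional character vector of length 2 with the record ids.
#' @return object of class `dnds_result`: list with `ids`, `method`,
#'   `kappa`, `Sd`, `Nd`, `S_sites`, `N_sites`, `pS`, `pN`, `dS`, `dN`,
#'   `dnds`, difference bookkeeping (`n_single`, `n_multi`, `n_identical`,
#'   `n_excluded`), and `undefined` (`NULL`, or the reason the ratio is
#'   undefined, in which case `dnds` is `NA`).
#' @examples
#' pair <- simulate_pair(n_codons = 300, substitutions_per_lineage = 30,
#'                       kappa = 4, seed = 1)
#' dnds_pair(pair$a, pair$b, method = "modified", kappa = 4)
#' @export
dnds_pair <- function(cds_a, cds_b, method = c("modified", "old"), kappa = 4,
                      sites = c("mean", "first"), jc_correction = FALSE,
                      code = "standard", ids = NULL) {
  method <- match.arg(method)
  sites <- match.arg(sites)
  gs_a <- gene_sites(cds_a, method, kappa, code,
                     id = if (!is.null(ids)) ids[1] else NULL)
  gs_b <- gene_sites(cds_b, method, kappa, code,
                     id = if (!is.null(ids)) ids[2] else NULL)
  dif <- count_codon_differences(cds_a, cds_b, code)
  S_sites <- if (sites == "mean") (gs_a$S_total + gs_b$S_total) / 2 else gs_a$S_total
  N_sites <- if (sites == "mean") (gs_a$N_total + gs_b$N_total) / 2 else gs_a$N_total

  undefined <- NULL
  pS <- if (S_sites > 0) dif$Sd / S_sites else NA_real_
  pN <- if (N_sites > 0) dif$Nd / N_sites else NA_real_
  dS <- pS
  dN <- pN
  if (jc_correction) {
    dS <- .jc_correct(pS)
    dN <- .jc_correct(pN)
  }
  if (dif$Sd == 0 || !is.finite(dS) || !is.finite(dN) || dS == 0) {
    undefined <- if (dif$Sd == 0) "no_synonymous_differences"
                 else "sites_or_correction_undefined"
    ratio <- NA_real_
  } else {
    ratio <- dN / dS
  }
  out <- list(ids = ids, method = method, kappa = gs_a$kappa,
              Sd = dif$Sd, Nd = dif$Nd,
              S_sites = S_sites, N_sites = N_sites,
              pS = pS, pN = pN, dS = dS, dN = dN, dnds = ratio,
              n_single = dif$n_single, n_multi = dif$n_multi,
              n_identical = dif$n_identical, n_excluded = dif$n_excluded,
              sites = sites, jc_correction = jc_correction,
              undefined = undefined)
  class(out) <- "dnds_result"
  out
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf("dN/dS (%s method%s)\n", x$method,
              if (is.na(x$kappa)) "" else sprintf(", kappa = %g", x$kappa)))
  if (!is.null(x$ids)) cat(sprintf("  pair: %s vs %s\n", x$ids[1], x$ids[2]))
  cat(sprintf("  Sd = %d, Nd = %d (single-substitution codons: %d; multi: %d excluded)\n",
              x$Sd, x$Nd, x$n_single, x$n_multi))
  cat(sprintf("  S sites = %.3f, N sites = %.3f; pS = %.5f, pN = %.5f\n",
              x$S_sites, x$N_sites, x$pS, x$pN))
  if (is.null(x$undefined)) {
    cat(sprintf("  dN/dS = %.4f\n", x$dnds))
  } else {
    cat(sprintf("  dN/dS undefined (%s)\n", x$undefined))
  }
  invisible(x)
}

#' Gene-level composition covariates
#'
#' Counts codons of two-fold degenerate amino acids (TFD), codons of the
#' strictly four-fold amino acids Val/Pro/Thr/Ala/Gly (FFD), their ratio,
#' and the fraction of pretermination codons. A terminal stop codon is
#' stripped; non-ACGT codons and internal stops are skipped.
#'
#' @inheritParams gene_sites
#' @return list with `n_tfd`, `n_ffd`, `tfd_ffd_ratio` (`NA` when
#'   `n_ffd = 0`), `pretermination_fraction`, `n_codons` (sense codons
#'   counted).
#' @examples
#' gene_composition("TGGTAT")  # pretermination_fraction = 1
#' @export
gene_composition <- function(cds, code = "standard") {
  dat <- .codon_data(code)
  cod <- .split_codons(.normalize_sequence(cds))
  if (length(cod) > 0L && cod[length(cod)] %in% dat$stops) {
    cod <- cod[-length(cod)]
  }
  cod <- cod[grepl("^[ACGT]{3}$", cod) & !(cod %in% dat$stops)]
  cls <- unname(dat$degeneracy[cod])
  n_tfd <- sum(cls == "twofold")
  n_ffd <- sum(cls == "fourfold")
  list(n_tfd = n_tfd, n_ffd = n_ffd,
       tfd_ffd_ratio = if (n_ffd > 0) n_tfd / n_ffd else NA_real_,
       pretermination_fraction = if (length(cod) > 0)
         mean(cod %in% dat$pretermination) else NA_real_,
       n_codons = length(cod))
}

#' Compare old and modified dN/dS over a set of gene pairs
#'
#' For each pair, computes dN/dS under both site models, the percent
#' increase `100 * (new - old) / old`, and the composition covariates
#' (TFD:FFD codon ratio and pretermination-codon fraction, pooled over the
#' two sequences). Pearson correlations between the percent increase and
#' each covariate are computed over the genes where all quantities are
#' defined (at least 3 required).
#'
#' @inheritParams sense_codons
#' @param pairs list of gene pairs; each element a list or character vector
#'   holding the two aligned equal-length CDS.
#' @param kappa transition:transversion ratio for the modified model.
#' @param sites site-averaging mode passed to [dnds_pair()].
#' @return list of class `dnds_method_comparison` with `genes` (data.frame:
#'   `id`, `Sd`, `Nd`, `dnds_old`, `dnds_new`, `percent_increase`,
#'   `tfd_ffd_ratio`, `pretermination_fraction`, `n_multi`), `n_usable`,
#'   and `r_tfd_ffd`, `p_tfd_ffd`, `r_pretermination`, `p_pretermination`
#'   (all `NA` when fewer than 3 genes are usable).
#' @export
compare_dnds_methods <- function(pairs, kappa = 4, sites = c("mean", "first"),
                                 code = "standard") {
  sites <- match.arg(sites)
  ids <- names(pairs)
  if (is.null(ids)) ids <- sprintf("gene_%03d", seq_along(pairs))
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    a <- p[[1]]
    b <- p[[2]]
    old <- dnds_pair(a, b, "old", code = code, sites = sites)
    new <- dnds_pair(a, b, "modified", kappa = kappa, code = code,
                     sites = sites)
    comp_a <- gene_composition(a, code)
    comp_b <- gene_composition(b, code)
    n_tfd <- comp_a$n_tfd + comp_b$n_tfd
    n_ffd <- comp_a$n_ffd + comp_b$n_ffd
    n_cod <- comp_a$n_codons + comp_b$n_codons
    pi <- if (!is.null(old$undefined) || !is.null(new$undefined) ||
              !is.finite(old$dnds) || old$dnds <= 0) NA_real_
          else 100 * (new$dnds - old$dnds) / old$dnds
    data.frame(id = ids[i], Sd = new$Sd, Nd = new$Nd,
               dnds_old = old$dnds, dnds_new = new$dnds,
               percent_increase = pi,
               tfd_ffd_ratio = if (n_ffd > 0) n_tfd / n_ffd else NA_real_,
               pretermination_fraction = if (n_cod > 0)
                 (comp_a$pretermination_fraction * comp_a$n_codons +
                    comp_b$pretermination_fraction * comp_b$n_codons) / n_cod
                 else NA_real_,
               n_multi = new$n_multi, stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, rows)
  .cor_or_na <- function(x, y) {
    use <- is.finite(x) & is.finite(y)
    if (sum(use) < 3L || stats::sd(x[use]) == 0 || stats::sd(y[use]) == 0) {
      return(list(r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(x[use], y[use], method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value)
  }
  ct_tfd <- .cor_or_na(genes$percent_increase, genes$tfd_ffd_ratio)
  ct_pre <- .cor_or_na(genes$percent_increase, genes$pretermination_fraction)
  out <- list(genes = genes,
              n_usable = sum(is.finite(genes$percent_increase)),
              r_tfd_ffd = ct_tfd$r, p_tfd_ffd = ct_tfd$p,
              r_pretermination = ct_pre$r, p_pretermination = ct_pre$p)
  class(out) <- "dnds_method_comparison"
  out
}

#' @export
print.dnds_method_comparison <- function(x, ...) {
  cat(sprintf("dN/dS method comparison over %d genes (%d usable)\n",
              nrow(x$genes), x$n_usable))
  pi <- x$genes$percent_increase
  if (any(is.finite(pi))) {
    cat(sprintf("  percent increase (modified vs old): %.1f%% to %.1f%%\n",
                min(pi, na.rm = TRUE), max(pi, na.rm = TRUE)))
  }
  cat(sprintf("  Pearson r vs TFD:FFD ratio: %.3f (p = %.3g)\n",
              x$r_tfd_ffd, x$p_tfd_ffd))
  cat(sprintf("  Pearson r vs pretermination fraction: %.3f (p = %.3g)\n",
              x$r_pretermination, x$p_pretermination))
  invisible(x)
}
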