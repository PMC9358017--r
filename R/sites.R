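# Per-codon synonymous / non-synonymous site values.
#
# Old (equal-rate) model:      S = (Sti + Stv) / 3
#                              NS = (Nti + Ntv) / 3
# Modified (kappa-weighted, nonsense-corrected) model:
#                              S  = (k*Sti + Stv) / (k + 2)
#                              NS = (k*(Nti - Nti_stop) + (Ntv - Ntv_stop)) / (k + 2)
# where k is the transition:transversion rate ratio. All values are small
# integers divided once by 3 or k+2, so doubles carry them exactly enough
# for stable 3-decimal rounding.

.check_kappa <- function(kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) ||
      kappa <= 0) {
    stop("kappa must be a single positive number", call. = FALSE)
  }
  as.numeric(kappa)
}

#' Round half away from zero to three decimals
#'
#' The rounding used for displayed site values (7/6 renders as 1.167).
#'
#' @param x numeric vector.
#' @return numeric vector rounded to 3 decimals.
#' @examples
#' round3(7 / 6)
#' @export
round3 <- function(x) sign(x) * floor(abs(x) * 1000 + 0.5) / 1000

#' Synonymous and non-synonymous site values of codons
#'
#' Computes per-codon S and NS site values under either the classic
#' equal-rate model (`method = "old"`) or the modified model
#' (`method = "modified"`) that weights transitions by `kappa` and removes
#' single-base changes to stop codons from the non-synonymous sites of
#' pretermination codons. Under the old model `S + NS = 3` exactly; under
#' the modified model the deficit from 3 is the weight of the removed
#' nonsense changes, `(kappa*Nti_stop + Ntv_stop)/(kappa + 2)`.
#'
#' @inheritParams substitution_profile
#' @param method `"modified"` (default) or `"old"`.
#' @param kappa transition:transversion rate ratio (> 0); ignored for
#'   `method = "old"`. Default 4, the E. coli estimate.
#' @return data.frame with columns `codon`, `method`, `kappa` (`NA` for the
#'   old method), `S`, `NS` (full precision; use [round3()] for display).
#' @examples
#' codon_sites("CTA", "modified", kappa = 4)  # S = 1.667
#' codon_sites("CTA", "old")                  # S = 1.333
#' @export
codon_sites <- function(codons, method = c("modified", "old"), kappa = 4,
                        code = "standard") {
  method <- match.arg(method)
  prof <- substitution_profile(codons, code)
  if (method == "old") {
    S <- (prof$Sti + prof$Stv) / 3
    NS <- (prof$Nti + prof$Ntv) / 3
    kappa <- NA_real_
  } else {
    kappa <- .check_kappa(kappa)
    S <- (kappa * prof$Sti + prof$Stv) / (kappa + 2)
    NS <- (kappa * (prof$Nti - prof$Nti_stop) +
             (prof$Ntv - prof$Ntv_stop)) / (kappa + 2)
  }
  data.frame(codon = prof$codon, method = method, kappa = kappa,
             S = S, NS = NS, stringsAsFactors = FALSE)
}

#' Full 61-codon site table
#'
#' One row per sense codon (alphabetical), with amino acid, degeneracy class
#' and pretermination status. Stop codons are not listed (their site values
#' are undefined).
#'
#' @inheritParams codon_sites
#' @return data.frame of class `site_table` with columns `codon`,
#'   `amino_acid`, `S`, `NS`, `degeneracy_class`, `is_pretermination`;
#'   attributes `method` and `kappa`.
#' @examples
#' tab <- site_table("modified", kappa = 4)
#' tab[tab$codon == "CGA", ]  # S = 7/6
#' @export
site_table <- function(method = c("modified", "old"), kappa = 4,
                       code = "standard") {
  method <- match.arg(method)
  dat <- .codon_data(code)
  st <- codon_sites(dat$sense, method, kappa, code)
  out <- data.frame(codon = st$codon,
                    amino_acid = unname(dat$aa[st$codon]),
                    S = st$S, NS = st$NS,
                    degeneracy_class = unname(dat$degeneracy[st$codon]),
                    is_pretermination = st$codon %in% dat$pretermination,
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  attr(out, "kappa") <- st$kappa[1]
  class(out) <- c("site_table", "data.frame")
  out
}

#' Column totals of a site table
#'
#' Sums the unrounded per-codon S and NS values. At kappa = 4 the modified
#' synonymous total is (4*62 + 72)/6 = 53.333; the old totals satisfy
#' `total_S + total_NS = 183` (61 codons x 3 sites).
#'
#' @param table a [site_table()].
#' @return list with `total_S` and `total_NS` (unrounded).
#' @examples
#' round3(site_table_totals(site_table("modified", 4))$total_S)  # 53.333
#' @export
site_table_totals <- function(table) {
  stopifnot(is.data.frame(table), all(c("S", "NS") %in% names(table)))
  list(total_S = sum(table$S), total_NS = sum(table$NS))
}
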