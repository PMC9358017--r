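# Codon substitution simulator: single-base substitution events with
# transition:transversion rate ratio kappa, missense acceptance probability
# omega (purifying selection), and rejection of nonsense changes. Used as
# the test harness for the site models, dN/dS and fS.

#' Draw one single-base substitution for a codon
#'
#' Samples one of the nine single-base neighbors with probability
#' proportional to kappa for each transition and 1 for each transversion,
#' i.e. kappa/(3*kappa + 6) per transition neighbor and 1/(3*kappa + 6) per
#' transversion neighbor. Uses the current R random number stream.
#'
#' @inheritParams codon_neighbors
#' @param kappa transition:transversion rate ratio (> 0).
#' @return one-row data.frame as in [codon_neighbors()].
#' @examples
#' set.seed(1)
#' draw_substitution("TTT", kappa = 4)
#' @export
draw_substitution <- function(codon, kappa = 4, code = "standard") {
  kappa <- .check_kappa(kappa)
  nb <- codon_neighbors(codon, code)
  w <- ifelse(nb$is_transition, kappa, 1)
  nb[sample.int(9L, 1L, prob = w), , drop = FALSE]
}

#' Random in-frame coding sequence
#'
#' Draws codons independently from the 61 sense codons, uniformly by
#' default or with the supplied usage weights. Uses the current R random
#' number stream.
#'
#' @inheritParams sense_codons
#' @param n_codons number of codons.
#' @param weights optional named numeric vector of codon usage weights
#'   (names are sense codons; codons absent from the vector get weight 0).
#' @return a single character string of length `3 * n_codons`.
#' @export
random_cds <- function(n_codons, weights = NULL, code = "standard") {
  dat <- .codon_data(code)
  if (is.null(weights)) {
    w <- rep(1, length(dat$sense))
  } else {
    if (is.null(names(weights))) stop("weights must be named by codon")
    w <- stats::setNames(rep(0, length(dat$sense)), dat$sense)
    w[normalize_codons(names(weights))] <- weights
    if (any(w < 0) || sum(w) <= 0) stop("weights must be non-negative with a positive sum")
  }
  paste(sample(dat$sense, n_codons, replace = TRUE, prob = w), collapse = "")
}

#' Apply accepted substitution events to a coding sequence
#'
#' Applies exactly `n_substitutions` accepted single-base substitution
#' events. Each event picks a codon uniformly at random, draws one of its
#' nine neighbors with Ti:Tv weights kappa:1, then accepts the change with
#' probability 1 if synonymous, `omega` if missense, and 0 if nonsense when
#' `reject_nonsense` is `TRUE` (`omega` otherwise). Rejected events are
#' redrawn (fresh codon and neighbor) until one is accepted.
#'
#' @inheritParams random_cds
#' @param reference in-frame sense-codon sequence (no stop codons, pure
#'   ACGT/U).
#' @param n_substitutions number of accepted events to apply.
#' @param kappa transition:transversion rate ratio (> 0).
#' @param omega missense acceptance probability in [0, 1] (1 = neutral).
#' @param reject_nonsense reject changes that create stop codons (default).
#' @param max_attempts per-event cap on rejected draws before erroring.
#' @return the mutated sequence (character string).
#' @examples
#' set.seed(1)
#' evolve_sequence(strrep("TTTGGA", 50), 10, kappa = 4)
#' @export
evolve_sequence <- function(reference, n_substitutions, kappa = 4, omega = 1,
                            reject_nonsense = TRUE, max_attempts = 10000L,
                            code = "standard") {
  kappa <- .check_kappa(kappa)
  if (!is.numeric(omega) || length(omega) != 1L || omega < 0 || omega > 1) {
    stop("omega must be a single number in [0, 1]", call. = FALSE)
  }
  if (n_substitutions < 0) stop("n_substitutions must be >= 0", call. = FALSE)
  dat <- .codon_data(code)
  cod <- .split_codons(.normalize_sequence(reference))
  if (any(!grepl("^[ACGT]{3}$", cod))) {
    stop("reference contains non-ACGT(U) characters", call. = FALSE)
  }
  if (any(cod %in% dat$stops)) {
    stop(sprintf("reference contains a stop codon at codon %d",
                 which(cod %in% dat$stops)[1]), call. = FALSE)
  }
  n <- length(cod)
  if (n == 0L && n_substitutions > 0) {
    stop("cannot substitute in an empty sequence", call. = FALSE)
  }
  sim <- dat$sim
  for (k in seq_len(n_substitutions)) {
    att <- 0L
    repeat {
      att <- att + 1L
      if (att > max_attempts) {
        stop(sprintf("no acceptable substitution found after %d attempts",
                     max_attempts), call. = FALSE)
      }
      i <- sample.int(n, 1L)
      nb <- sim[[cod[i]]]
      j <- sample.int(9L, 1L, prob = ifelse(nb$ti, kappa, 1))
      e <- nb$eff[j]
      p_acc <- if (e == 1L) 1 else if (e == 2L) omega
               else if (reject_nonsense) 0 else omega
      if (p_acc >= 1 || (p_acc > 0 && stats::runif(1L) < p_acc)) {
        cod[i] <- nb$target[j]
        break
      }
    }
  }
  paste(cod, collapse = "")
}

#' Simulate a star-shaped multi-strain codon alignment
#'
#' Generates (or takes) a reference CDS and evolves `n_sequences`
#' independent descendants from it with [evolve_sequence()]. The reference
#' is included as the first record (`"reference"`); descendants are named
#' `strain_0001`, `strain_0002`, ... Defaults emulate a bacterial core-gene
#' strain panel: kappa = 4 (the E. coli transition:transversion estimate),
#' neutral synonymous evolution (omega = 1), nonsense changes rejected, and
#' a substitution load of 2% of codons per strain when
#' `substitutions_per_sequence` is not given.
#'
#' @inheritParams evolve_sequence
#' @param reference reference CDS; if `NULL`, one is drawn with
#'   [random_cds()].
#' @param n_codons reference length when `reference` is `NULL`.
#' @param n_sequences number of derived strains.
#' @param substitutions_per_sequence accepted events per strain (default
#'   `round(0.02 * n_codons)`).
#' @param seed optional integer seed (`set.seed()` is called when given).
#' @param weights codon usage weights for the generated reference.
#' @return named character vector of equal-length sequences, reference
#'   first, with the simulation settings in `attr(, "config")`.
#' @examples
#' aln <- simulate_alignment(n_codons = 200, n_sequences = 5,
#'                           substitutions_per_sequence = 10, seed = 1)
#' @export
simulate_alignment <- function(reference = NULL, n_codons = 1000,
                               n_sequences = 100,
                               substitutions_per_sequence = NULL,
                               kappa = 4, omega = 1, reject_nonsense = TRUE,
                               seed = NULL, weights = NULL,
                               code = "standard") {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(reference)) {
    reference <- random_cds(n_codons, weights, code)
  } else {
    reference <- .normalize_sequence(reference)
    n_codons <- nchar(reference) %/% 3L
  }
  if (is.null(substitutions_per_sequence)) {
    substitutions_per_sequence <- max(1L, round(0.02 * n_codons))
  }
  if (n_sequences < 1L) stop("n_sequences must be >= 1", call. = FALSE)
  seqs <- vapply(seq_len(n_sequences), function(i) {
    evolve_sequence(reference, substitutions_per_sequence, kappa, omega,
                    reject_nonsense, code = code)
  }, character(1))
  out <- c(reference = reference,
           stats::setNames(seqs, sprintf("strain_%04d", seq_len(n_sequences))))
  attr(out, "config") <- list(
    n_codons = n_codons, n_sequences = n_sequences,
    substitutions_per_sequence = substitutions_per_sequence, kappa = kappa,
    omega = omega, reject_nonsense = reject_nonsense, seed = seed)
  out
}

#' Simulate a divergent pair of coding sequences
#'
#' Evolves two independent copies of a common ancestor, the standard setup
#' for pairwise dN/dS calibration.
#'
#' @inheritParams simulate_alignment
#' @param substitutions_per_lineage accepted events on each of the two
#'   lineages.
#' @return list with `a`, `b` (the two descendant sequences) and
#'   `reference` (the ancestor).
#' @export
simulate_pair <- function(reference = NULL, n_codons = 1000,
                          substitutions_per_lineage = 100, kappa = 4,
                          omega = 1, reject_nonsense = TRUE, seed = NULL,
                          weights = NULL, code = "standard") {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(reference)) {
    reference <- random_cds(n_codons, weights, code)
  } else {
    reference <- .normalize_sequence(reference)
  }
  list(a = evolve_sequence(reference, substitutions_per_lineage, kappa,
                           omega, reject_nonsense, code = code),
       b = evolve_sequence(reference, substitutions_per_lineage, kappa,
                           omega, reject_nonsense, code = code),
       reference = reference)
}

#' Estimate kappa from synonymous third-position polymorphism
#'
#' At the third position of four-fold degenerate and family-box codons every
#' change is synonymous and each site offers exactly 1 transition and 2
#' transversion options, so under neutrality the synonymous Ti:Tv count
#' ratio at such sites is kappa:2. The estimator is
#' `kappa_hat = 2 * Ti / Tv` over those SNPs. By default observations are
#' weighted by carrier strain count, which keeps the estimator consistent
#' when the same substitution recurs in several strains.
#'
#' @inheritParams extract_snps
#' @param count `"strains"` (default, weight by `allele_count`) or
#'   `"alleles"` (distinct alleles count once).
#' @return list with `kappa_hat` (`NA` with an `undefined` flag when no
#'   transversion is observed), `n_transition`, `n_transversion`,
#'   `n_informative`.
#' @export
estimate_kappa <- function(alignment, reference_id = "reference",
                           count = c("strains", "alleles"),
                           code = "standard") {
  count <- match.arg(count)
  snps <- extract_snps(alignment, reference_id, code = code)
  if (nrow(snps) == 0L) {
    return(list(kappa_hat = NA_real_, n_transition = 0, n_transversion = 0,
                n_informative = 0, undefined = "no_informative_snps"))
  }
  cls <- degeneracy_class(snps$ref_codon, code)
  inf <- snps$codon_position == 3L & snps$effect == "synonymous" &
    cls %in% c("fourfold", "sixfold_family")
  w <- if (count == "strains") snps$allele_count else rep(1L, nrow(snps))
  ti <- sum(w[inf & snps$is_transition])
  tv <- sum(w[inf & !snps$is_transition])
  if (tv == 0) {
    return(list(kappa_hat = NA_real_, n_transition = ti, n_transversion = 0,
                n_informative = ti, undefined = "no_transversions_observed"))
  }
  list(kappa_hat = 2 * ti / tv, n_transition = ti, n_transversion = tv,
       n_informative = ti + tv, undefined = NULL)
}
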