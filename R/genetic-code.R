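# Genetic-code machinery: single-base codon neighborhoods, Ti/Tv
# classification, substitution effects (synonymous / missense / nonsense),
# degeneracy classes and pretermination codons. Everything downstream (site
# values, dN/dS, fS, the simulator) is built on the 9-neighbor enumeration
# cached here, one entry per genetic code.

.cs_cache <- new.env(parent = emptyenv())

.BASES <- c("A", "C", "G", "T")

.is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

#' Normalize codon strings to the internal DNA alphabet
#'
#' Upper-cases, maps U to T (RNA input is accepted everywhere) and validates
#' that each element is a triplet over A/C/G/T.
#'
#' @param x character vector of codons (DNA or RNA, any case).
#' @param what label used in error messages.
#' @return character vector of upper-case DNA codons.
#' @examples
#' normalize_codons(c("aug", "TTT"))
#' @export
normalize_codons <- function(x, what = "codon") {
  x <- toupper(as.character(x))
  x <- chartr("U", "T", x)
  bad <- !grepl("^[ACGT]{3}$", x)
  if (any(bad)) {
    stop(sprintf("invalid %s '%s': must be a triplet over A, C, G, T or U",
                 what, x[bad][1]), call. = FALSE)
  }
  x
}

# Normalize a full nucleotide sequence; leaves ambiguity codes and gaps as-is.
.normalize_sequence <- function(x) chartr("U", "T", toupper(as.character(x)))

# Split an in-frame sequence into codons.
.split_codons <- function(x, id = NULL) {
  n <- nchar(x)
  if (n %% 3L != 0L) {
    stop(sprintf("sequence%s has length %d, not a multiple of 3 (not in frame)",
                 if (is.null(id)) "" else sprintf(" '%s'", id), n),
         call. = FALSE)
  }
  if (n == 0L) return(character(0))
  substring(x, seq.int(1L, n, 3L), seq.int(3L, n, 3L))
}

# Load (and cache) everything derived from one genetic code. `code` is
# "standard", an NCBI translation-table id understood by
# Biostrings::getGeneticCode(), or a path to a two-column TSV
# (codon, amino_acid; stops as "*") like the one shipped in inst/extdata.
.codon_data <- function(code = "standard") {
  key <- as.character(code)[1]
  hit <- get0(key, envir = .cs_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)

  if (identical(key, "standard")) {
    aa <- Biostrings::GENETIC_CODE
  } else if (file.exists(key)) {
    tab <- utils::read.table(key, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    aa <- stats::setNames(tab$amino_acid, normalize_codons(tab$codon))
  } else {
    aa <- Biostrings::getGeneticCode(key)
  }
  aa <- aa[order(names(aa))]
  if (length(aa) != 64L) stop("genetic code table must have 64 codons")
  codons <- names(aa)
  sense <- codons[aa != "*"]
  stops <- codons[aa == "*"]

  neighbors <- lapply(codons, function(cd) {
    b <- strsplit(cd, "", fixed = TRUE)[[1]]
    pos <- rep(1:3, each = 3L)
    alt <- unlist(lapply(1:3, function(p) setdiff(.BASES, b[p])),
                  use.names = FALSE)
    target <- vapply(seq_along(pos), function(i) {
      t <- b
      t[pos[i]] <- alt[i]
      paste(t, collapse = "")
    }, character(1))
    ref <- b[pos]
    effect <- if (aa[cd] == "*") {
      ifelse(aa[target] == "*", "nonsense", "missense")
    } else {
      ifelse(aa[target] == "*", "nonsense",
             ifelse(aa[target] == unname(aa[cd]), "synonymous", "missense"))
    }
    data.frame(codon = cd, position = pos, ref_base = ref, alt_base = alt,
               target = target, is_transition = .is_transition(ref, alt),
               effect = unname(effect), stringsAsFactors = FALSE)
  })
  names(neighbors) <- codons

  profile <- do.call(rbind, lapply(sense, function(cd) {
    nb <- neighbors[[cd]]
    syn <- nb$effect == "synonymous"
    non <- nb$effect == "nonsense"
    data.frame(codon = cd, amino_acid = unname(aa[cd]),
               Sti = sum(syn & nb$is_transition),
               Stv = sum(syn & !nb$is_transition),
               Nti = sum(!syn & nb$is_transition),
               Ntv = sum(!syn & !nb$is_transition),
               Nti_stop = sum(non & nb$is_transition),
               Ntv_stop = sum(non & !nb$is_transition),
               stringsAsFactors = FALSE)
  }))
  rownames(profile) <- profile$codon

  # Degeneracy classes derived from the code table itself: amino acids with
  # 6 codons are split into the 4-codon family box (shared first two bases)
  # and the 2-codon split box.
  cls <- character(length(sense))
  names(cls) <- sense
  for (a in unique(aa[sense])) {
    cs <- sense[aa[sense] == a]
    n <- length(cs)
    if (n == 1L) cls[cs] <- "onefold"
    else if (n == 2L) cls[cs] <- "twofold"
    else if (n == 3L) cls[cs] <- "threefold"
    else if (n == 4L) cls[cs] <- "fourfold"
    else {
      pre <- substr(cs, 1, 2)
      box <- names(which(table(pre) == 4L))
      cls[cs] <- ifelse(pre %in% box, "sixfold_family", "sixfold_split")
    }
  }

  # Light per-codon view used by the simulator (covers stop codons too, so
  # the simulator can optionally let nonsense changes through).
  sim <- lapply(neighbors, function(nb) {
    list(target = nb$target, ti = nb$is_transition,
         eff = match(nb$effect, c("synonymous", "missense", "nonsense")))
  })

  out <- list(code = key, aa = aa, codons = codons, sense = sense,
              stops = stops, neighbors = neighbors, profile = profile,
              degeneracy = cls,
              pretermination = profile$codon[profile$Nti_stop +
                                             profile$Ntv_stop >= 1L],
              sim = sim)
  assign(key, out, envir = .cs_cache)
  out
}

.stop_check <- function(codons, dat) {
  hit <- codons %in% dat$stops
  if (any(hit)) {
    stop(sprintf("'%s' is a stop codon; sense codon required", codons[hit][1]),
         call. = FALSE)
  }
  invisible(codons)
}

#' Sense and stop codons of a genetic code
#'
#' @param code genetic code: `"standard"` (default), an NCBI translation
#'   table id accepted by [Biostrings::getGeneticCode()], or a path to a
#'   two-column TSV (`codon`, `amino_acid`, stops as `"*"`).
#' @return character vector of codons, alphabetical.
#' @examples
#' length(sense_codons())  # 61
#' stop_codons()           # TAA, TAG, TGA
#' @export
sense_codons <- function(code = "standard") .codon_data(code)$sense

#' @rdname sense_codons
#' @export
stop_codons <- function(code = "standard") .codon_data(code)$stops

#' Translate codons to amino acids
#'
#' @inheritParams sense_codons
#' @param codons character vector of codons (DNA or RNA).
#' @return character vector of one-letter amino acids (`"*"` for stops).
#' @examples
#' translate_codons(c("ATG", "UUU", "TAA"))
#' @export
translate_codons <- function(codons, code = "standard") {
  dat <- .codon_data(code)
  unname(dat$aa[normalize_codons(codons)])
}

#' Enumerate the nine single-base neighbors of a sense codon
#'
#' Every codon position can change to three alternative bases, giving nine
#' single-substitution neighbors: always 3 transitions and 6 transversions.
#' Each neighbor is classified as synonymous, missense or nonsense under the
#' genetic code. Ordering is deterministic: position 1 to 3, alternative base
#' in A < C < G < T order.
#'
#' @inheritParams sense_codons
#' @param codon a single sense codon (DNA or RNA).
#' @return data.frame with 9 rows and columns `codon`, `position` (1-3),
#'   `ref_base`, `alt_base`, `target`, `is_transition`, `effect`.
#' @examples
#' codon_neighbors("TTT")
#' @export
codon_neighbors <- function(codon, code = "standard") {
  dat <- .codon_data(code)
  cd <- normalize_codons(codon)
  if (length(cd) != 1L) stop("codon_neighbors() takes a single codon")
  .stop_check(cd, dat)
  nb <- dat$neighbors[[cd]]
  rownames(nb) <- NULL
  nb
}

#' Classify one single-base substitution in a codon
#'
#' @inheritParams codon_neighbors
#' @param position codon position, 1, 2 or 3.
#' @param alt_base replacement base (must differ from the reference base).
#' @return list with `target`, `is_transition` and `effect` (one of
#'   `"synonymous"`, `"missense"`, `"nonsense"`).
#' @examples
#' classify_substitution("CGA", 1, "T")  # nonsense transition (-> TGA)
#' @export
classify_substitution <- function(codon, position, alt_base,
                                  code = "standard") {
  nb <- codon_neighbors(codon, code)
  position <- as.integer(position)
  alt_base <- chartr("U", "T", toupper(alt_base))
  row <- nb[nb$position == position & nb$alt_base == alt_base, ]
  if (nrow(row) != 1L) {
    stop(sprintf("no substitution %s -> %s at position %d of %s",
                 substr(normalize_codons(codon), position, position),
                 alt_base, position, normalize_codons(codon)), call. = FALSE)
  }
  list(target = row$target, is_transition = row$is_transition,
       effect = row$effect)
}

#' Per-codon substitution profile
#'
#' Counts the nine single-base neighbors of each sense codon partitioned
#' into synonymous/non-synonymous x transition/transversion, plus the
#' subset of non-synonymous changes that create stop codons (`Nti_stop`,
#' `Ntv_stop`). For every sense codon `Sti + Stv + Nti + Ntv = 9`,
#' `Sti + Nti = 3` and `Stv + Ntv = 6`.
#'
#' @inheritParams sense_codons
#' @param codons character vector of sense codons.
#' @return data.frame with one row per input codon and columns `codon`,
#'   `amino_acid`, `Sti`, `Stv`, `Nti`, `Ntv`, `Nti_stop`, `Ntv_stop`.
#' @examples
#' substitution_profile(c("TGG", "TTT"))
#' @export
substitution_profile <- function(codons, code = "standard") {
  dat <- .codon_data(code)
  cds <- normalize_codons(codons)
  .stop_check(cds, dat)
  out <- dat$profile[cds, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pretermination codons
#'
#' Sense codons one single-base substitution away from a stop codon. Under
#' the standard code there are 18 such codons carrying 23 nonsense
#' substitutions in total; five codons (TTA, TCA, TGG, TAT, TAC) have two
#' nonsense neighbors each.
#'
#' @inheritParams sense_codons
#' @return character vector of codons, alphabetical.
#' @examples
#' length(pretermination_codons())  # 18
#' @export
pretermination_codons <- function(code = "standard") {
  sort(.codon_data(code)$pretermination)
}

#' Degeneracy class of sense codons
#'
#' Classes are derived from the code table: `onefold` (Met, Trp),
#' `twofold` (Phe, Tyr, Cys, His, Gln, Asn, Lys, Asp, Glu), `threefold`
#' (Ile), `fourfold` (Val, Pro, Thr, Ala, Gly), and for the six-codon amino
#' acids (Leu, Arg, Ser) `sixfold_family` (the four-codon box sharing its
#' first two bases: CTN, CGN, TCN) vs `sixfold_split` (TTA, TTG, AGA, AGG,
#' AGT, AGC).
#'
#' @inheritParams substitution_profile
#' @return character vector of class labels, one per input codon.
#' @examples
#' degeneracy_class(c("GGG", "TTT", "AGC"))
#' @export
degeneracy_class <- function(codons, code = "standard") {
  dat <- .codon_data(code)
  cds <- normalize_codons(codons)
  .stop_check(cds, dat)
  unname(dat$degeneracy[cds])
}
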