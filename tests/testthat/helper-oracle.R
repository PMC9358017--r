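# Independent brute-force oracle over the standard genetic code, written
# against the raw code table with plain loops so it shares no enumeration
# logic with the package.

oracle_aa <- Biostrings::GENETIC_CODE

oracle_neighbors <- function(codon) {
  b <- strsplit(codon, "", fixed = TRUE)[[1]]
  rows <- list()
  for (p in 1:3) {
    for (alt in c("A", "C", "G", "T")) {
      if (alt == b[p]) next
      t <- b
      t[p] <- alt
      target <- paste(t, collapse = "")
      ti <- paste(sort(c(b[p], alt)), collapse = "") %in% c("AG", "CT")
      aa_t <- oracle_aa[[target]]
      eff <- if (aa_t == "*") "nonsense"
             else if (aa_t == oracle_aa[[codon]]) "synonymous"
             else "missense"
      rows[[length(rows) + 1L]] <- data.frame(
        position = p, alt_base = alt, target = target, is_transition = ti,
        effect = eff, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

oracle_profile <- function(codon) {
  nb <- oracle_neighbors(codon)
  syn <- nb$effect == "synonymous"
  non <- nb$effect == "nonsense"
  c(Sti = sum(syn & nb$is_transition), Stv = sum(syn & !nb$is_transition),
    Nti = sum(!syn & nb$is_transition), Ntv = sum(!syn & !nb$is_transition),
    Nti_stop = sum(non & nb$is_transition),
    Ntv_stop = sum(non & !nb$is_transition))
}

oracle_sense <- sort(names(oracle_aa)[oracle_aa != "*"])
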