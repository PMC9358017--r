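# The published 61-codon S/NS site tables, transcribed from the code-table
# layout (outer rows: first base U/C/A/G; inner rows: third base U/C/A/G;
# columns: second base U/C/A/G; stop codons NA). Values are the printed
# 3-decimal cells.

.published_table <- function(cells) {
  firsts <- c("T", "C", "A", "G")
  seconds <- c("T", "C", "A", "G")
  thirds <- c("T", "C", "A", "G")
  out <- data.frame(codon = character(0), S = numeric(0), NS = numeric(0),
                    stringsAsFactors = FALSE)
  k <- 0L
  for (f in firsts) {
    for (t3 in thirds) {
      for (s in seconds) {
        k <- k + 1L
        out <- rbind(out, data.frame(
          codon = paste0(f, s, t3),
          S = cells[[k]][1], NS = cells[[k]][2], stringsAsFactors = FALSE))
      }
    }
  }
  out <- out[!is.na(out$S), ]
  out[order(out$codon), ]
}

# Equal-rate (old) method table.
published_table_old <- .published_table(list(
  # U block, third = U, C, A, G
  c(0.333, 2.667), c(1.000, 2.000), c(0.333, 2.667), c(0.333, 2.667),
  c(0.333, 2.667), c(1.000, 2.000), c(0.333, 2.667), c(0.333, 2.667),
  c(0.667, 2.333), c(1.000, 2.000), c(NA, NA),       c(NA, NA),
  c(0.667, 2.333), c(1.000, 2.000), c(NA, NA),       c(0.000, 3.000),
  # C block
  c(1.000, 2.000), c(1.000, 2.000), c(0.333, 2.667), c(1.000, 2.000),
  c(1.000, 2.000), c(1.000, 2.000), c(0.333, 2.667), c(1.000, 2.000),
  c(1.333, 1.667), c(1.000, 2.000), c(0.333, 2.667), c(1.333, 1.667),
  c(1.333, 1.667), c(1.000, 2.000), c(0.333, 2.667), c(1.333, 1.667),
  # A block
  c(0.667, 2.333), c(1.000, 2.000), c(0.333, 2.667), c(0.333, 2.667),
  c(0.667, 2.333), c(1.000, 2.000), c(0.333, 2.667), c(0.333, 2.667),
  c(0.667, 2.333), c(1.000, 2.000), c(0.333, 2.667), c(0.667, 2.333),
  c(0.000, 3.000), c(1.000, 2.000), c(0.333, 2.667), c(0.667, 2.333),
  # G block
  c(1.000, 2.000), c(1.000, 2.000), c(0.333, 2.667), c(1.000, 2.000),
  c(1.000, 2.000), c(1.000, 2.000), c(0.333, 2.667), c(1.000, 2.000),
  c(1.000, 2.000), c(1.000, 2.000), c(0.333, 2.667), c(1.000, 2.000),
  c(1.000, 2.000), c(1.000, 2.000), c(0.333, 2.667), c(1.000, 2.000)))

# kappa = 4 (modified) method table. The printed NS cell for GGA (2.000)
# omits GGA's nonsense neighbor (GGA -> TGA, a first-position transversion);
# the formula value is 11/6 = 1.833. The acceptance test treats that single
# cell as a printed erratum.
published_table_modified_k4 <- .published_table(list(
  # U block, third = U, C, A, G
  c(0.667, 2.333), c(1.000, 2.000), c(0.667, 2.000), c(0.667, 2.167),
  c(0.667, 2.333), c(1.000, 2.000), c(0.667, 2.000), c(0.667, 2.167),
  c(1.333, 1.333), c(1.000, 1.667), c(NA, NA),       c(NA, NA),
  c(1.333, 1.500), c(1.000, 1.833), c(NA, NA),       c(0.000, 1.667),
  # C block
  c(1.000, 2.000), c(1.000, 2.000), c(0.667, 2.333), c(1.000, 2.000),
  c(1.000, 2.000), c(1.000, 2.000), c(0.667, 2.333), c(1.000, 2.000),
  c(1.667, 1.333), c(1.000, 2.000), c(0.667, 1.667), c(1.167, 1.167),
  c(1.667, 1.333), c(1.000, 2.000), c(0.667, 1.667), c(1.167, 1.833),
  # A block
  c(0.833, 2.167), c(1.000, 2.000), c(0.667, 2.333), c(0.667, 2.333),
  c(0.833, 2.167), c(1.000, 2.000), c(0.667, 2.333), c(0.667, 2.333),
  c(0.333, 2.667), c(1.000, 2.000), c(0.667, 2.167), c(0.833, 2.000),
  c(0.000, 3.000), c(1.000, 2.000), c(0.667, 2.167), c(0.833, 2.167),
  # G block
  c(1.000, 2.000), c(1.000, 2.000), c(0.667, 2.333), c(1.000, 2.000),
  c(1.000, 2.000), c(1.000, 2.000), c(0.667, 2.333), c(1.000, 2.000),
  c(1.000, 2.000), c(1.000, 2.000), c(0.667, 2.167), c(1.000, 2.000),
  c(1.000, 2.000), c(1.000, 2.000), c(0.667, 2.167), c(1.000, 2.000)))
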