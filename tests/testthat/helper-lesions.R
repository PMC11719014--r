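# Random lesion scenarios for property tests: non-overlapping substitutions,
# ambiguities and short indels, with an occasional trailing unsequenced mask.
random_scenarios <- function(locus, n_taxa, seed, p_mask = 0.1) {
  L <- locus$exonic_length
  n_exons <- nrow(locus$exons)
  withr::with_seed(seed, {
    out <- list()
    for (i in seq_len(n_taxa)) {
      les <- list()
      claimed <- integer(0)
      if (stats::runif(1) < p_mask && n_exons >= 3) {
        from <- sample(seq(n_exons - 1L, n_exons), 1)
        les <- c(les, list(lesion_mask(from, n_exons)))
        off <- cumsum(locus$exons$end - locus$exons$start)
        mask_start <- off[from - 1L] + 1L
        claimed <- c(claimed, seq(mask_start - 12L, L))
      }
      for (j in seq_len(sample(0:4, 1))) {
        type <- sample(c("del", "ins", "sub", "amb"), 1,
                       prob = c(0.3, 0.2, 0.35, 0.15))
        for (try in 1:25) {
          pos <- sample(5:(L - 12L), 1)
          len <- sample(1:6, 1)
          span <- if (type == "del") pos:(pos + len - 1L) else pos
          if (any(c(span, span + 1L) %in% claimed)) next
          les <- c(les, list(switch(type,
            del = lesion_deletion(pos, len),
            ins = lesion_insertion(pos, paste(
              sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = "")),
            sub = lesion_point(pos, sample(c("A", "C", "G", "T"), 1)),
            amb = lesion_ambiguity(pos, sample(c("R", "Y", "W", "N"), 1))
          )))
          claimed <- c(claimed, span, span + 1L)
          break
        }
      }
      out[[sprintf("t%03d", i)]] <- les
    }
    out
  })
}
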