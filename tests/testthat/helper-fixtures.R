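# Shared hand-built fixtures with countable answers.

# ten-probe fixture: 2 invalid gene ids, 3 probes above background in only
# 40% of their samples, 5 fully retained probes -> 5 survive the filter
toy_probes <- function() {
  probes <- sprintf("p%02d", 1:10)
  genes <- c("gA", "gA", "gB", "gB", "gC", "gC", "gD", NA, "", "gE")
  rows <- list()
  for (i in 1:10) {
    above <- if (i %in% c(3, 5, 7)) rep(c(TRUE, FALSE, FALSE, TRUE, FALSE), 2)
             else rep(TRUE, 10)
    rows[[i]] <- data.frame(
      probe_id = probes[i], gene_id = genes[i],
      donor_id = rep(c("d1", "d2"), each = 5),
      sample_id = sprintf("s%02d_%d", 1:10, i),
      parcel_label = rep(1:5, 2),
      intensity = seq(0, 9) + i * 0.1,
      above_background = above, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
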