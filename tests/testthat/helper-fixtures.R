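# A tiny deterministic PRO-seq differential table: one row per consensus
# scenario, enumerable by hand.
#   pk1: 3 conditions pass            -> keep
#   pk2: 2 pass                       -> drop
#   pk3: 4 pass                       -> keep
#   pk4: logfc 0 fails strict <, 3 pass -> keep
#   pk5: p = 0.1 fails strict <, 2 pass -> drop
#   pk6: up-regulated everywhere      -> drop
proseq_fixture <- function() {
  conds <- c("A549_3h", "A549_6h", "H460_3h", "H460_6h")
  tbl <- tibble::tibble(chrom = "chr1",
                        start = seq(1000, by = 1000, length.out = 6),
                        end = seq(1600, by = 1000, length.out = 6),
                        name = paste0("pk", 1:6))
  lfc <- rbind(c(-1, -1, -1, 1),
               c(-1, -1, 1, 1),
               c(-1, -1, -1, -1),
               c(0, -1, -1, -1),
               c(-1, -1, -1, -1),
               c(1, 1, 1, 1))
  p <- rbind(c(0.01, 0.01, 0.01, 0.5),
             c(0.01, 0.01, 0.01, 0.01),
             c(0.05, 0.05, 0.05, 0.05),
             c(0.01, 0.01, 0.01, 0.01),
             c(0.1, 0.1, 0.01, 0.01),
             c(0.01, 0.01, 0.01, 0.01))
  for (j in seq_along(conds)) {
    tbl[[paste0("logfc_", conds[j])]] <- lfc[, j]
    tbl[[paste0("p_", conds[j])]] <- p[, j]
  }
  tbl
}
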