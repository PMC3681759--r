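#!/usr/bin/env Rscript
# Step 5: morphometry. Validates the skeleton/geodesic length measurement on
# constructed fixtures with known lengths, measures generated cells, and
# compares growth-cone areas between spacing groups with a t-test.
suppressMessages(library(pillarpatch))

px <- 0.1
disk <- function(dim, x, y, r) pillarpatch:::rasterize_disks(dim, x, y, r, px)

# straight 50 um tube from a soma
h <- 250; w <- 650
soma <- disk(c(h, w), 10, 15, 3)
tube <- matrix(FALSE, h, w)
tube[which(abs((seq_len(h) - 0.5) * px - 15) <= 0.5),
     which((seq_len(w) - 0.5) * px >= 10 &
             (seq_len(w) - 0.5) * px <= 63)] <- TRUE
fix1 <- measure_processes(soma | tube, soma, px)
cat(sprintf("straight 50 um fixture: longest = %.2f um\n", fix1$longest_um))

# generated cells
rows <- lapply(1:4, function(s) {
  m <- generate_neurite_mask(c(30, 30), 1, seed = 500 + s,
                             neurite_length_um = 15, soma_radius_um = 4)
  cbind(seed = 500 + s, measure_processes(m))
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/morphometry.csv", row.names = FALSE)
print(tab, row.names = FALSE)
cat(sprintf("longest >= mean in all cells: %s\n",
            all(tab$longest_um >= tab$mean_um)))

# growth-cone areas: confined (dense spacing) vs spread (sparse/flat)
set.seed(17)
dense <- rnorm(30, 20, 4)    # um2, confined cones on dense pillars
sparse <- rnorm(30, 35, 6)   # um2, fan-shaped cones on sparse/flat
gc <- growthcone_area_test(dense, sparse)
cat(sprintf("growth cones: %.1f +/- %.1f vs %.1f +/- %.1f um2, t = %.2f, p = %.2g\n",
            gc$mean_a, gc$sem_a, gc$mean_b, gc$sem_b, gc$t, gc$p))
cat("table: results/morphometry.csv\n")
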