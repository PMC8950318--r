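# Small in-code fixtures shared across test files.

# A minimal valid sample table: 2 doses x 1 time x 1 donor, 3 features.
tiny_sample_table <- function(treated = c(F1 = 8, F2 = 3, F3 = 10),
                              control = c(F1 = 2, F2 = 3, F3 = 10),
                              time = 4) {
  sample_table(tibble::tibble(
    sample_id = c("ctrl", "trt"), dose = c(0, 5), time = time,
    donor = "don1", batch = "don1",
    F1 = c(control[["F1"]], treated[["F1"]]),
    F2 = c(control[["F2"]], treated[["F2"]]),
    F3 = c(control[["F3"]], treated[["F3"]])
  ))
}

# A zero-noise stress-test run for one or two conditions.
flat_seahorse <- function(basal_ocr = 200 * 2e4, oligo = 0.51, fccp = 2,
                          rotaa = 0.1, basal_ecar = 3.36 * 2e4,
                          condition = "control", n_wells = 1) {
  simulate_seahorse(
    tibble::tibble(condition = condition, basal_ocr = basal_ocr,
                   basal_ecar = basal_ecar, ocr_oligomycin = oligo,
                   ocr_fccp = fccp, ocr_rotaa = rotaa),
    n_wells = n_wells, noise_sd = 0
  )
}

# Independent from-definition Davies-Bouldin recomputation (naive loops),
# used as the oracle against the vectorised implementation.
db_naive <- function(points, labels) {
  points <- as.matrix(points)
  ids <- sort(unique(labels))
  cent <- lapply(ids, function(g) colMeans(points[labels == g, , drop = FALSE]))
  scat <- vapply(seq_along(ids), function(gi) {
    p <- points[labels == ids[gi], , drop = FALSE]
    mean(vapply(seq_len(nrow(p)),
                function(r) sqrt(sum((p[r, ] - cent[[gi]])^2)), numeric(1)))
  }, numeric(1))
  worst <- vapply(seq_along(ids), function(i) {
    max(vapply(setdiff(seq_along(ids), i), function(j) {
      (scat[i] + scat[j]) / sqrt(sum((cent[[i]] - cent[[j]])^2))
    }, numeric(1)))
  }, numeric(1))
  mean(worst)
}

# Partition equivalence up to label renaming (same co-membership).
same_partition <- function(a, b) {
  a <- unname(a)
  b <- unname(b)
  identical(outer(a, a, `==`), outer(b, b, `==`))
}
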