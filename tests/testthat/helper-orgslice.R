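# build a bare marker trajectory from parallel time/score vectors
traj <- function(time_h, score, case_id = "C1", marker = "Ki67",
                 arm = "doxo") {
  out <- data.frame(case_id = case_id, marker = marker, arm = arm,
                    time_h = time_h, score = score,
                    stringsAsFactors = FALSE)
  class(out) <- c("marker_trajectory", "data.frame")
  out
}

# bliss_grid with a constant excess, for summary-call tests
constant_grid <- function(x, n = 7) {
  structure(list(drug_a = "a", drug_b = "b",
                 doses_a = seq_len(n), doses_b = seq_len(n),
                 A = rep(0.5, n), B = rep(0.5, n),
                 O = matrix(0.75 + x, n, n), E = matrix(0.75, n, n),
                 X = matrix(x, n, n), n_clamped = 0L),
            class = "bliss_grid")
}
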