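# Fast in-memory cell populations for the binding/sweep tests (no spatial
# placement; the magnet model only needs colour/activated flags).
make_population <- function(n_red_act, n_green_act, n_off = 0) {
  n <- n_red_act + n_green_act + n_off
  tibble::tibble(
    cell_id = seq_len(n),
    x_um = runif(n, 0, 100), y_um = runif(n, 0, 100),
    colour = c(rep("red", n_red_act), rep("green", n_green_act),
               rep(c("red", "green"), length.out = n_off)),
    activated = c(rep(TRUE, n_red_act + n_green_act), rep(FALSE, n_off)),
    bound = FALSE
  )
}

monod_up <- function(K, fmax = 1, f0 = 0, n = 1) {
  dose_response(f0, fmax, K = K, n = n, shape = "monotone_up")
}
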