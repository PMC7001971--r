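# Shared synthetic fixtures built in code at test time.

donor_ref <- gen_spectrum(517, 15, skew = 2)
acceptor_ref <- gen_spectrum(593, 20, skew = 2)

ng <- fluorophore("mNeonGreen")
scarlet_i <- fluorophore("mScarlet-I")

# one cell centered in a small frame
single_cell_spec <- function(f, radius = 5, center = c(8, 8), ...) {
  list(list(center = center, radius = radius, f = f, ...))
}

# grid of k non-overlapping cells for image tests
grid_cell_specs <- function(k, radius = 6, pitch = 20, expression = 500,
                            f = 0.9, per_row = 3) {
  lapply(seq_len(k), function(i) {
    list(center = c(((i - 1) %/% per_row) * pitch + radius + 4,
                    ((i - 1) %% per_row) * pitch + radius + 4),
         radius = radius, expression = expression, f = f)
  })
}
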