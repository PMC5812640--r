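# shared fixtures, built once per test run
.fixtures <- new.env(parent = emptyenv())

default_phantom <- function() {
  if (is.null(.fixtures$phantom))
    .fixtures$phantom <- build_phantom(phantom_config(), seed = 1)
  .fixtures$phantom
}

# phantom with the routine-RT effect applied, zero noise
effect_phantom <- function() {
  if (is.null(.fixtures$effect_phantom))
    .fixtures$effect_phantom <- apply_radiation_effect(
      default_phantom(), radiation_effect(), rt_type = "routine")
  .fixtures$effect_phantom
}

# world coordinates (mm) of voxel centres for a phantom grid
phantom_world <- function(ph) {
  co <- r1ratio:::grid_coords(dim(ph$labels), ph$voxel_mm)
  list(x = co[[1]], y = co[[2]], z = co[[3]])
}

# exhaustive two-sided Mann-Whitney p-value by enumerating every assignment
# of the pooled ranks to group A (assumes no ties)
mw_exact_p <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  u_all <- apply(combos, 2, function(ix) sum(ix) - n1 * (n1 + 1) / 2)
  mu <- mean(u_all)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}
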