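# Shared fixtures built in code: protein constants, bare interfaces, and a
# brute-force contact oracle used to validate the cell-list implementation.

coe3 <- get_protein("COE-3")

d2o <- contrast_solvent("D2O", SLD_D2O)
cm4 <- contrast_solvent("CM4", 4.0e-6)
h2o <- contrast_solvent("H2O", SLD_H2O)

# Si/solvent interface with no oxide: reduces the stack to a single
# interface so the matrix code can be checked against the Fresnel formula.
bare_interface_stack <- function(roughness = 0) {
  layer_stack(list(), coe3,
              substrate(oxide_thickness = 0, oxide_roughness = roughness))
}

# Closed-form Fresnel reflectivity of a single interface (independent oracle).
fresnel_r <- function(q, sld_front, sld_back, sigma = 0) {
  k0 <- q / 2
  k1 <- sqrt(as.complex((q / 2)^2 - 4 * pi * (sld_back - sld_front)))
  r <- (k0 - k1) / (k0 + k1)
  if (sigma > 0) r <- r * exp(-2 * k0 * k1 * sigma^2)
  Mod(r)^2
}

# O(N^2) pairwise contact count (independent oracle for the cell list).
brute_contact_count <- function(protein, surface, cutoff = 5) {
  pp <- protein$xyz; sp <- surface$xyz
  n <- 0L
  for (i in seq_len(nrow(pp))) {
    d2 <- (sp[, 1] - pp[i, 1])^2 + (sp[, 2] - pp[i, 2])^2 + (sp[, 3] - pp[i, 3])^2
    if (any(d2 <= cutoff^2)) n <- n + 1L
  }
  n
}

# Random atom cloud helper
random_atoms <- function(n, lim = 30, seed = NULL, group = "protein") {
  if (!is.null(seed)) set.seed(seed)
  atom_set(matrix(runif(3 * n, -lim, lim), ncol = 3),
           mass = runif(n, 1, 16), group = rep(group, n))
}
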