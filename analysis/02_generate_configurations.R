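#!/usr/bin/env Rscript
# Builds the synthetic study configurations at the tabulated 0.15 GPa
# densities: hydrogen-bond-seeking hard-core packings of 300 molecules for a
# water-rich (x = 0.1) and a methanol-rich (x = 0.7) mixture, an ideal-gas
# null fixture, and the periodic diamond network whose ring census is known
# exactly. Writes extended-xyz files plus JSON ground truth under
# results/configs/.

library(liqstruct)

dir.create("results/configs", showWarnings = FALSE, recursive = TRUE)

for (x in c(0.1, 0.7)) {
  for (s in 1:4) {
    cfg <- generate_mixture_packing(300, lookup_density(x, 0.15), x,
                                    seed = s)
    write_configuration(cfg, sprintf("results/configs/mixture_x%02d_seed%d.xyz",
                                     round(100 * x), s))
  }
  cat(sprintf("packed 4 seeds at x = %.1f (rho = %.4f / A^3)\n",
              x, lookup_density(x, 0.15)))
}

ig <- generate_ideal_gas(1000, lookup_density(0, 0.15), seed = 1)
write_configuration(ig, "results/configs/ideal_gas_water.xyz")
cat(sprintf("ideal gas: 1000 molecules, box %.2f A\n", ig$box[1]))

dn <- generate_diamond_network(3)
write_configuration(dn$config, "results/configs/diamond_network.xyz")
jsonlite::write_json(list(adjacency = dn$adjacency,
                          lattice_constant = dn$lattice_constant),
                     "results/configs/diamond_ground_truth.json")
cat(sprintf("diamond network: %d molecules, %d ground-truth bonds\n",
            n_molecules(dn$config), nrow(dn$adjacency)))
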