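# Shared definition of the synthetic study set: a 2x2 cocoa-butter-like
# design (emulsifier x shear type) whose cell morphologies follow the void
# structures seen in shear-crystallized lipids. Sourced by the numbered
# stage scripts so every stage regenerates identical volumes from the seeds.

dims <- c(96L, 96L, 96L)
vox_um <- 16
cells <- c("CBlike RS", "CBlike LS", "CBlike/M RS", "CBlike/M LS")

cell_spec <- function(cell, seed) {
  switch(cell,
    "CBlike RS" = phantom_spec("bubbles", dims, vox_um, seed,
                               radius_params = list(meanlog = log(50),
                                                    sdlog = 0.25),
                               target_void_fraction = 0.11),
    "CBlike LS" = phantom_spec("bubbles", dims, vox_um, seed,
                               radius_params = list(meanlog = log(50),
                                                    sdlog = 0.25),
                               target_void_fraction = 0.02),
    "CBlike/M RS" = phantom_spec("bubbles", dims, vox_um, seed,
                                 radius_params = list(meanlog = log(45),
                                                      sdlog = 0.25),
                                 target_void_fraction = 0.022),
    "CBlike/M LS" = phantom_spec("cracks", dims, vox_um, seed,
                                 crack_params = list(n_planes = 3,
                                                     thickness_vox = 2.2)))
}

cell_design <- data.frame(
  cell = cells,
  emulsifier = c(FALSE, FALSE, TRUE, TRUE),
  shear_type = c("RS", "LS", "RS", "LS"))
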