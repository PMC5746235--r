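# the acceptance file carries deliberately-red expectations (documented
# paper/spec mismatches); keep the runner from terminating the whole suite
# at the default failure cap so every file still executes
options(testthat.progress.max_fails = 1000L)

# shared lazily-built meshes (kept across tests within one file run)
.fixtures <- new.env(parent = emptyenv())

get_mesh <- function(nx, ny = nx, h = 1, d = 0.5 * h, seed = 1L) {
  key <- paste(nx, ny, h, d, seed, sep = "_")
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- vrl_mesh(mesh_spec(nx, ny, h, d, d, seed))
  .fixtures[[key]]
}
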