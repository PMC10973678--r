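# Shared fixtures and independent oracles for the test suite.

# Brute-force excitation-matrix oracle: literal loop over the sequencing
# rules, independent of the package's vectorized builder.
oracle_protocol <- function(n, d, s) {
  wrap <- function(i) (i - 1L) %% n + 1L
  rows <- NULL
  for (vp in seq_len(n)) {
    vm <- wrap(vp + d)
    mm <- wrap(vm + 1L)
    while (mm != vm) {
      mp <- wrap(mm + s)
      if (!(mm %in% c(vp, vm)) && !(mp %in% c(vp, vm)))
        rows <- rbind(rows, c(vp, vm, mp, mm))
      mm <- wrap(mm + 1L)
    }
  }
  rows
}

# Small shared geometry (built once per test run; building is cheap but
# the pixel locator cache makes reuse worthwhile)
tiny_mesh <- function() build_disk_mesh(radius = 1, n_electrodes = 8, refinement = 1)
tiny_protocol <- function() build_protocol(eit_protocol_config(8, 3, 1))

bath_mesh <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- build_disk_mesh()
    val
  }
})

device_protocol <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- build_protocol()
    val
  }
})
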