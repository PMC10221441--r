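# Shared fixtures and a session-level cache so expensive PC-SAFT solves
# (binodal crossings, tie lines) are computed once and reused across tests.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

fixture_params <- function() memo("params", loadParameters("dohrn2023"))
naproxen_system <- function() memo("sysn", ternarySystem(fixture_params(), "naproxen"))
venetoclax_system <- function() memo("sysv", ternarySystem(fixture_params(), "venetoclax"))

T37 <- 310.15
T50 <- 323.15
P0 <- 1e5

ven_crossing <- function(dl) {
  memo(paste0("venx", dl), binodalCrossing(venetoclax_system(), T37, P0, dl))
}

# random simplex points under a fixed seed
simplex_points <- function(n, k = 3, seed = 42) {
  set.seed(seed)
  m <- matrix(stats::rexp(n * k), n, k)
  m / rowSums(m)
}
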