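## shared fixtures; expensive objects are computed once per test run
.fix <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .fix, inherits = FALSE))
    assign(key, fn(), envir = .fix)
  get(key, envir = .fix, inherits = FALSE)
}

ep_default <- function() epi_params()
cp_default <- function() cell_params()

grid40 <- function() pop_grid(40, 40)
grid60 <- function() pop_grid(60, 60)

## preheated drug-free state on the 60x60 grid, shared across files
preheated60 <- function() {
  cached("ph60", function() preheat(ep_default(), cp_default(),
                                    grid = grid60())$state)
}

## inert dynamics: no motion, no death, no division — handy baseline
cp_inert <- function(...) {
  args <- utils::modifyList(list(beta0 = 0, beta10 = 0, gamma0 = 0,
                                 gamma1 = 0, v0 = 0, sigma = 0, K = 1e6),
                            list(...))
  do.call(cell_params, args)
}

no_dose <- function() dose_schedule("constant", c_const = 0)
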