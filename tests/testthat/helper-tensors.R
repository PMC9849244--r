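# shared helpers: internal accessors and tiny tensor fixtures

ns <- asNamespace("slhardnet")

rand4 <- function(h, w, c, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::rnorm(h * w * c * n), dim = c(h, w, c, n))
}

# set every parameter of a module (sub)tree to zero
zero_module <- function(mod) {
  for (p in ns$collect_params(mod)) p$val[] <- 0
  invisible(mod)
}

node_value <- function(x) if (inherits(x, "ag_node")) x$v else x

# run fn under a fresh tape and return the loss node after backward
with_backward <- function(fn) {
  ns$ag_tape_start()
  on.exit(ns$ag_tape_end())
  root <- fn()
  ns$ag_backward(root)
  root
}

sigmoid <- function(z) 1 / (1 + exp(-z))
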