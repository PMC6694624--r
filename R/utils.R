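# Activations are kept as names so that fitted models serialize to text.
# Derivatives are expressed in terms of the activation OUTPUT, which is
# exact for the supported families and avoids storing pre-activations.

.activations <- c("sigmoid", "identity", "tanh")

.act_fun <- function(name) {
  switch(name,
    sigmoid  = function(x) 1 / (1 + exp(-x)),
    identity = function(x) x,
    tanh     = function(x) tanh(x),
    stop("unknown activation '", name, "'", call. = FALSE)
  )
}

# derivative d act(x) / dx written as a function of y = act(x)
.act_deriv_from_output <- function(name) {
  switch(name,
    sigmoid  = function(y) y * (1 - y),
    identity = function(y) if (is.matrix(y)) array(1, dim(y)) else rep(1, length(y)),
    tanh     = function(y) 1 - y^2,
    stop("unknown activation '", name, "'", call. = FALSE)
  )
}

.check_activation <- function(name) {
  if (!is.character(name) || length(name) != 1L || !name %in% .activations) {
    stop("activation must be one of: ", paste(.activations, collapse = ", "),
         call. = FALSE)
  }
  name
}

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

.is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

.is_nonneg <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. seed = NULL uses (and advances) the current
# stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Independent named sub-streams derived from one master seed, so that e.g.
# parameter initialization is unaffected by how many corruption draws an
# epoch consumes. Values stay below 2^31.
.derive_seeds <- function(seed, n, what = "stream") {
  .with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

.clip01 <- function(x, eps = 1e-12) pmin(pmax(x, eps), 1 - eps)
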