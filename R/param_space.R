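#' Construct a mixed-type assembler parameter space
#'
#' A parameter space is an ordered table of parameter definitions for a
#' transcript assembler. Each row defines one tunable parameter: its name,
#' its kind (`"binary"`, `"integer"` or `"float"`), its default value on the
#' native scale, and the step size the coordinate-ascent warmup uses along
#' that coordinate. Row order is meaningful: it fixes the coordinate index
#' of every parameter vector over the space.
#'
#' @param specs A data frame with columns `name`, `kind`, `default` and
#'   (optionally) `warmup_step`. Missing `warmup_step` values are filled with
#'   the package convention: `max(1, round(default / 5))` for integers,
#'   `default / 5` for floats (or `0.1` when the default is at most `0.1`),
#'   and `1` (a flip) for binary parameters.
#' @param assembler Label for the assembler this space describes.
#'
#' @return A tibble of class `param_space` with columns `name`, `kind`,
#'   `default`, `warmup_step` and an `assembler` attribute.
#' @examples
#' param_space(
#'   data.frame(name = c("on", "depth"), kind = c("binary", "integer"),
#'              default = c(0, 10)),
#'   assembler = "toy"
#' )
#' @export
param_space <- function(specs, assembler = "custom") {
  specs <- as_tibble(specs)
  required <- c("name", "kind", "default")
  missing_cols <- setdiff(required, names(specs))
  if (length(missing_cols) > 0) {
    abort(paste0("`specs` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(specs$name)) abort("parameter names must be unique")
  if (!all(specs$kind %in% c("binary", "integer", "float"))) {
    abort("`kind` must be one of \"binary\", \"integer\", \"float\"")
  }
  specs$default <- as.numeric(specs$default)
  if (any(specs$kind != "binary" & specs$default < 0)) {
    abort("non-binary defaults must be nonnegative")
  }
  if (any(specs$kind == "binary" & !specs$default %in% c(0, 1))) {
    abort("binary defaults must be 0 or 1")
  }
  if (any(specs$kind == "integer" & specs$default != round(specs$default))) {
    abort("integer defaults must be integral")
  }
  if (!"warmup_step" %in% names(specs)) specs$warmup_step <- NA_real_
  specs$warmup_step <- as.numeric(specs$warmup_step)
  fill <- is.na(specs$warmup_step)
  specs$warmup_step[fill] <- default_warmup_step(
    specs$kind[fill], specs$default[fill]
  )
  if (any(specs$kind != "binary" & specs$warmup_step <= 0)) {
    abort("warmup_step must be positive for non-binary parameters")
  }
  out <- specs[, c("name", "kind", "default", "warmup_step")]
  attr(out, "assembler") <- assembler
  class(out) <- c("param_space", class(out))
  out
}

default_warmup_step <- function(kind, default) {
  step <- numeric(length(kind))
  step[kind == "binary"] <- 1
  int <- kind == "integer"
  step[int] <- pmax(1, round(default[int] / 5))
  flt <- kind == "float"
  step[flt] <- ifelse(default[flt] <= 0.1, 0.1, default[flt] / 5)
  step
}

#' Load a bundled assembler parameter registry
#'
#' Returns the shipped parameter registry for a supported transcript
#' assembler: Scallop v0.10.2 (18 tunable parameters) or StringTie2 v2.2.1
#' (8 tunable parameters), with each parameter's kind and default on its
#' native scale. Registries are stored as plain-text tables under
#' `inst/extdata/param_spaces/` so they can be inspected and versioned.
#'
#' @param assembler One of `"scallop"` or `"stringtie2"`.
#' @return A [param_space()] tibble.
#' @examples
#' builtin_space("scallop")
#' @export
builtin_space <- function(assembler) {
  assembler <- tolower(assembler)
  path <- system.file("extdata", "param_spaces",
                      paste0(assembler, ".tsv"), package = "asmtune")
  if (!nzchar(path)) {
    abort(paste0("unknown assembler \"", assembler,
                 "\"; available: scallop, stringtie2"))
  }
  specs <- read.delim(path, stringsAsFactors = FALSE)
  param_space(specs, assembler = assembler)
}

#' Default parameter vector of a space
#'
#' @param space A [param_space()].
#' @return A named numeric vector in space order.
#' @export
default_vector <- function(space) {
  stopifnot(inherits(space, "param_space"))
  setNames(space$default, space$name)
}

#' Initial search domain of a parameter space
#'
#' Every non-binary parameter gets the closed range `[0, 10 * default]`
#' (integers restricted to the integer lattice inside it); binary parameters
#' are fixed to `{0, 1}`.
#'
#' @param space A [param_space()].
#' @return A tibble of class `search_domain` with columns `name`, `kind`,
#'   `lo`, `hi`.
#' @examples
#' initial_domain(builtin_space("stringtie2"))
#' @export
initial_domain <- function(space) {
  stopifnot(inherits(space, "param_space"))
  out <- tibble(
    name = space$name,
    kind = space$kind,
    lo = 0,
    hi = ifelse(space$kind == "binary", 1, 10 * space$default)
  )
  attr(out, "initial_hi") <- setNames(out$hi, out$name)
  class(out) <- c("search_domain", class(out))
  out
}

#' Re-center a search domain on a warmup incumbent
#'
#' After the coordinate-ascent warmup returns an incumbent `theta_hat`, the
#' range of every non-binary coordinate `i` is reset to
#' `[0, max(2 * theta_hat[i], U_i)]`, where `U_i` is that coordinate's
#' initial upper bound. Binary coordinates are unchanged. Upper bounds
#' therefore never shrink below their initial values and the incumbent is
#' always contained in the adjusted domain.
#'
#' @param domain A `search_domain` produced by [initial_domain()].
#' @param theta_hat Named numeric parameter vector conformable with `domain`.
#' @return A new `search_domain`.
#' @export
adjust_domain <- function(domain, theta_hat) {
  stopifnot(inherits(domain, "search_domain"))
  theta_hat <- conform_theta(theta_hat, domain$name)
  init_hi <- attr(domain, "initial_hi")
  if (is.null(init_hi)) init_hi <- setNames(domain$hi, domain$name)
  out <- domain
  nb <- domain$kind != "binary"
  out$lo[nb] <- 0
  out$hi[nb] <- pmax(2 * theta_hat[nb], init_hi[nb])
  attr(out, "initial_hi") <- init_hi
  out
}

conform_theta <- function(theta, names) {
  if (length(theta) != length(names)) {
    abort(paste0("parameter vector has length ", length(theta),
                 " but the space has ", length(names), " coordinates"))
  }
  if (!is.null(names(theta))) {
    if (!setequal(names(theta), names)) {
      abort("parameter vector names do not match the space")
    }
    theta <- theta[names]
  } else {
    names(theta) <- names
  }
  theta
}

#' Validate a parameter vector against a space and domain
#'
#' @param space A [param_space()].
#' @param theta Named numeric vector in space order.
#' @param domain Optional `search_domain`; defaults to [initial_domain()].
#' @return `TRUE` iff every coordinate is type-valid (integral for integer
#'   parameters, 0/1 for binary ones) and lies inside the domain.
#' @export
validate_vector <- function(space, theta, domain = initial_domain(space)) {
  stopifnot(inherits(space, "param_space"))
  theta <- conform_theta(theta, space$name)
  if (any(!is.finite(theta))) return(FALSE)
  int <- space$kind == "integer"
  if (any(theta[int] != round(theta[int]))) return(FALSE)
  bin <- space$kind == "binary"
  if (any(!theta[bin] %in% c(0, 1))) return(FALSE)
  all(theta >= domain$lo & theta <= domain$hi)
}

#' Project a raw numeric vector onto a space's lattice and domain
#'
#' Rounds integer coordinates to the nearest lattice point, snaps binary
#' coordinates to 0/1, and clips everything into the domain. Used to map
#' continuous acquisition-function optimizers back onto the mixed space.
#'
#' @inheritParams validate_vector
#' @return A valid named parameter vector.
#' @export
project_vector <- function(space, theta, domain = initial_domain(space)) {
  theta <- conform_theta(theta, space$name)
  theta <- pmin(pmax(theta, domain$lo), domain$hi)
  int <- space$kind == "integer"
  theta[int] <- pmin(pmax(round(theta[int]), ceiling(domain$lo[int])),
                     floor(domain$hi[int]))
  bin <- space$kind == "binary"
  theta[bin] <- as.numeric(theta[bin] >= 0.5)
  theta
}

#' @export
print.param_space <- function(x, ...) {
  cat("<param_space> assembler:", attr(x, "assembler"),
      "-", nrow(x), "parameters\n")
  NextMethod()
}
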