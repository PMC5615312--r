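# Isotropic linear-elastic material registry.
#
# Internal unit system is SI (Pa, m). Constructors accept the units the
# tissue-engineering literature prints (kPa, MPa, um) and convert at the
# boundary.

.material_registry <- new.env(parent = emptyenv())

#' Define an isotropic linear-elastic material
#'
#' @param name Short label, e.g. `"G5"`.
#' @param modulus Young's modulus of the bulk solid, in the unit given by
#'   `unit`.
#' @param poisson Poisson's ratio, in `[0, 0.5)`.
#' @param unit Unit of `modulus`: `"Pa"`, `"kPa"`, `"MPa"` or `"GPa"`.
#'
#' @return An object of class `"scaffold_material"` with fields `name`,
#'   `E` (Pa) and `nu`.
#' @examples
#' material("agarose", 30, 0.45, unit = "kPa")
#' @export
material <- function(name, modulus, poisson, unit = "kPa") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  E <- as_pascal(modulus, unit)
  if (!is.finite(E) || E <= 0)
    stop("elastic modulus must be positive and finite", call. = FALSE)
  if (!is.finite(poisson) || poisson < 0 || poisson >= 0.5)
    stop("Poisson's ratio must lie in [0, 0.5)", call. = FALSE)
  structure(list(name = name, E = E, nu = poisson),
            class = "scaffold_material")
}

as_pascal <- function(x, unit) {
  fac <- switch(match.arg(unit, c("Pa", "kPa", "MPa", "GPa")),
                Pa = 1, kPa = 1e3, MPa = 1e6, GPa = 1e9)
  as.numeric(x) * fac
}

#' Built-in scaffold materials
#'
#' The five materials commonly simulated for stiffness-tunable scaffolds:
#' gelatin at 5, 7 and 14 wt% (`G5`, `G7`, `G14`; 40, 63 and 110 kPa, Poisson
#' 0.4), chitosan (2.53 kPa, Poisson 0.3) and polycaprolactone (`PCL`,
#' 400 MPa, Poisson 0.3).
#'
#' @return Named list of [material()] objects.
#' @export
builtin_materials <- function() {
  list(
    G5       = material("G5",       40,    0.4, "kPa"),
    G7       = material("G7",       63,    0.4, "kPa"),
    G14      = material("G14",      110,   0.4, "kPa"),
    chitosan = material("chitosan", 2.53,  0.3, "kPa"),
    PCL      = material("PCL",      400,   0.3, "MPa")
  )
}

#' Register a custom material for lookup by name
#'
#' Registered materials are found by [get_material()] alongside the
#' built-ins; a registered name shadows a built-in of the same name.
#'
#' @param mat A [material()] object.
#' @return The material, invisibly.
#' @export
register_material <- function(mat) {
  stopifnot(inherits(mat, "scaffold_material"))
  assign(tolower(mat$name), mat, envir = .material_registry)
  invisible(mat)
}

#' Look up a material by name
#'
#' Lookup is case-insensitive and covers the built-ins plus anything added
#' with [register_material()]. A `scaffold_material` object passes through
#' unchanged.
#'
#' @param x Material name or `scaffold_material` object.
#' @return A `scaffold_material`.
#' @export
get_material <- function(x) {
  if (inherits(x, "scaffold_material")) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  key <- tolower(x)
  if (exists(key, envir = .material_registry, inherits = FALSE))
    return(get(key, envir = .material_registry, inherits = FALSE))
  builtins <- builtin_materials()
  hit <- match(key, tolower(names(builtins)))
  if (is.na(hit))
    stop(sprintf("unknown material '%s'; built-ins are %s", x,
                 paste(names(builtins), collapse = ", ")), call. = FALSE)
  builtins[[hit]]
}

#' Table of known materials
#'
#' @return A data.frame with columns `name`, `E_kPa`, `poisson`, `source`.
#' @export
material_table <- function() {
  builtins <- builtin_materials()
  custom <- mget(ls(.material_registry), envir = .material_registry)
  rows <- c(builtins, custom)
  src <- c(rep("builtin", length(builtins)), rep("custom", length(custom)))
  data.frame(
    name    = vapply(rows, `[[`, "", "name"),
    E_kPa   = vapply(rows, function(m) m$E / 1e3, 0),
    poisson = vapply(rows, `[[`, 0, "nu"),
    source  = src,
    row.names = NULL
  )
}

#' @export
print.scaffold_material <- function(x, ...) {
  cat(sprintf("<material> %s: E = %s, Poisson %.3g\n",
              x$name, format_pressure(x$E), x$nu))
  invisible(x)
}

# Pretty-print a pressure in the most natural unit.
format_pressure <- function(pa) {
  if (pa >= 1e9)      sprintf("%.4g GPa", pa / 1e9)
  else if (pa >= 1e6) sprintf("%.4g MPa", pa / 1e6)
  else if (pa >= 1e3) sprintf("%.4g kPa", pa / 1e3)
  else                sprintf("%.4g Pa",  pa)
}
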