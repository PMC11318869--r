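#' Build a reduced multicompartment morphology
#'
#' Constructs a deterministic compartmental tree with a single somatic root,
#' an apical trunk, oblique side branches attached along the trunk, and basal
#' dendrites attached to the soma. The layout is a reduced, analytically
#' tractable stand-in for a layer-5 pyramidal cell: the tree topology, the
#' four region labels (soma, basal, oblique, apical) and the per-compartment
#' synapse layout mirror the structure of detailed reconstructions while
#' keeping the compartment count configurable.
#'
#' Compartments are indexed so that every parent precedes its children, with
#' the soma at index 1 (parent index -1). Units are micrometres for geometry,
#' ohm centimetres for axial resistivity, microfarad per square centimetre
#' for specific capacitance and siemens per square centimetre for the leak
#' density; derived quantities (membrane area, capacitance in nF, leak and
#' axial conductances in nS) are computed at construction.
#'
#' @param n_basal,n_oblique,n_apical number of compartments per region
#'   (non-negative; total including the soma must be at least 2).
#' @param geometry_params optional named list overriding any of the defaults
#'   returned by [default_geometry()].
#' @return An object of class `nd_morphology`: a list with a `compartments`
#'   data frame (`parent`, `x`, `y`, `z`, `length`, `diameter`, `region`,
#'   `area`, `cap_nF`, `g_leak_nS`, `g_axial_nS`) and the passive constants.
#' @examples
#' m <- build_morphology(8, 4, 8)
#' m$n_comp
#' table(m$compartments$region)
#' @export
build_morphology <- function(n_basal, n_oblique, n_apical,
                             geometry_params = list()) {
  stopifnot(n_basal >= 0, n_oblique >= 0, n_apical >= 0)
  n_comp <- 1L + n_basal + n_oblique + n_apical
  if (n_comp < 2L)
    stop("morphology must contain at least 2 compartments (got ", n_comp, ")")
  geo <- utils::modifyList(default_geometry(), geometry_params)
  for (nm in c("soma_length", "soma_diameter", "apical_length",
               "apical_diameter", "oblique_length", "oblique_diameter",
               "basal_length", "basal_diameter", "axial_resistivity",
               "membrane_capacitance")) {
    if (!is.numeric(geo[[nm]]) || geo[[nm]] <= 0)
      stop("geometry parameter '", nm, "' must be strictly positive")
  }
  if (geo$leak_conductance <= 0) stop("leak_conductance must be positive")

  parent <- integer(n_comp)
  region <- character(n_comp)
  len <- dia <- x <- y <- z <- numeric(n_comp)

  parent[1] <- -1L
  region[1] <- "soma"
  len[1] <- geo$soma_length
  dia[1] <- geo$soma_diameter
  x[1] <- y[1] <- z[1] <- 0

  idx <- 2L
  # apical trunk: a single chain growing in +y
  apical_ids <- integer(0)
  if (n_apical > 0) {
    apical_ids <- idx:(idx + n_apical - 1L)
    prev <- 1L
    y0 <- geo$soma_length / 2
    for (k in seq_len(n_apical)) {
      i <- apical_ids[k]
      parent[i] <- prev
      region[i] <- "apical"
      len[i] <- geo$apical_length
      dia[i] <- geo$apical_diameter
      x[i] <- 0
      y[i] <- y0 + (k - 0.5) * geo$apical_length
      z[i] <- 0
      prev <- i
    }
    idx <- idx + n_apical
  }
  # obliques: single-compartment twigs spread along the proximal trunk
  if (n_oblique > 0) {
    attach_pool <- if (n_apical > 0) apical_ids else rep(1L, n_oblique)
    for (k in seq_len(n_oblique)) {
      i <- idx
      at <- attach_pool[((k - 1L) %% length(attach_pool)) + 1L]
      parent[i] <- at
      region[i] <- "oblique"
      len[i] <- geo$oblique_length
      dia[i] <- geo$oblique_diameter
      side <- if (k %% 2L == 0L) 1 else -1
      x[i] <- side * (dia[at] / 2 + geo$oblique_length / 2)
      y[i] <- y[at]
      z[i] <- 10 * ((k - 1L) %/% (2L * max(1L, length(attach_pool))))
      idx <- idx + 1L
    }
  }
  # basal dendrites: two chains from the soma growing in -y
  if (n_basal > 0) {
    n1 <- ceiling(n_basal / 2)
    for (branch in 1:2) {
      nb <- if (branch == 1) n1 else n_basal - n1
      if (nb == 0) next
      prev <- 1L
      sgn <- if (branch == 1) -1 else 1
      for (k in seq_len(nb)) {
        i <- idx
        parent[i] <- prev
        region[i] <- "basal"
        len[i] <- geo$basal_length
        dia[i] <- geo$basal_diameter
        x[i] <- sgn * k * geo$basal_length * 0.5
        y[i] <- -(geo$soma_length / 2 + (k - 0.5) * geo$basal_length * 0.87)
        z[i] <- 0
        prev <- i
        idx <- idx + 1L
      }
    }
  }

  area <- pi * dia * len                       # µm², cylinder lateral area
  cap_nF <- geo$membrane_capacitance * area * 1e-5
  g_leak_nS <- geo$leak_conductance * area * 10

  # axial conductance to the parent: two half-compartment series resistances
  ra_ohm_um <- geo$axial_resistivity * 1e4     # Ω·cm -> Ω·µm
  half_r <- ra_ohm_um * (len / 2) / (pi * (dia / 2)^2)  # Ω
  g_axial_nS <- numeric(n_comp)
  for (i in 2:n_comp)
    g_axial_nS[i] <- 1e9 / (half_r[i] + half_r[parent[i]])

  comp <- data.frame(parent = parent, x = x, y = y, z = z,
                     length = len, diameter = dia, region = region,
                     area = area, cap_nF = cap_nF, g_leak_nS = g_leak_nS,
                     g_axial_nS = g_axial_nS)
  structure(list(compartments = comp,
                 n_comp = n_comp,
                 soma_index = 1L,
                 axial_resistivity = geo$axial_resistivity,
                 membrane_capacitance = geo$membrane_capacitance,
                 leak_conductance = geo$leak_conductance,
                 leak_reversal = geo$leak_reversal),
            class = "nd_morphology")
}

#' Default geometry and passive parameters
#'
#' Values are in the range standard for cortical pyramidal-cell models:
#' axial resistivity 100 ohm cm, specific capacitance 1 uF/cm2, leak density
#' 5e-5 S/cm2 (membrane time constant 20 ms), leak reversal -70 mV.
#'
#' @return named list of geometry defaults (micrometre lengths/diameters).
#' @export
default_geometry <- function() {
  list(soma_length = 20, soma_diameter = 20,
       apical_length = 20, apical_diameter = 2.5,
       oblique_length = 20, oblique_diameter = 1.2,
       basal_length = 20, basal_diameter = 1.5,
       axial_resistivity = 100,          # Ω·cm
       membrane_capacitance = 1,         # µF/cm²
       leak_conductance = 5e-5,          # S/cm²
       leak_reversal = -70)              # mV
}

#' @export
print.nd_morphology <- function(x, ...) {
  cat("<nd_morphology> ", x$n_comp, " compartments (",
      paste(names(table(x$compartments$region)),
            table(x$compartments$region), sep = ":", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

validate_morphology <- function(morph) {
  stopifnot(inherits(morph, "nd_morphology"))
  p <- morph$compartments$parent
  if (sum(p == -1L) != 1L || p[1] != -1L)
    stop("morphology must have exactly one root (the soma, index 1)")
  if (any(p[-1] >= seq_along(p)[-1]) || any(p[-1] < 1L))
    stop("parents must precede children")
  if (sum(morph$compartments$region == "soma") != 1L)
    stop("exactly one soma compartment required")
  invisible(morph)
}

#' Serialize / read a morphology as JSON
#'
#' @param morph an `nd_morphology`.
#' @param path file path to write to / read from.
#' @return `read_morphology` returns the reconstructed `nd_morphology`.
#' @export
write_morphology <- function(morph, path) {
  validate_morphology(morph)
  obj <- list(compartments = morph$compartments,
              n_comp = morph$n_comp, soma_index = morph$soma_index,
              axial_resistivity = morph$axial_resistivity,
              membrane_capacitance = morph$membrane_capacitance,
              leak_conductance = morph$leak_conductance,
              leak_reversal = morph$leak_reversal)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_morphology
#' @export
read_morphology <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$compartments$parent <- as.integer(obj$compartments$parent)
  obj$n_comp <- as.integer(obj$n_comp)
  obj$soma_index <- as.integer(obj$soma_index)
  structure(obj, class = "nd_morphology")
}
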