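# A small generic Lennard-Jones / Coulomb / harmonic-angle parameter set.
# These are generic literature-style values (CHARMM/UFF magnitude class),
# shipped so the energy descriptors are well defined and reproducible; any
# other parameter table can be substituted via loadForcefield() or by
# editing the list.  Energies are in kcal/mol, distances in Angstrom.

.default_lj <- data.frame(
  element = c("H", "C", "N", "O", "S", "F", "Cl", "Br", "I", "P"),
  eps = c(0.030, 0.070, 0.170, 0.155, 0.250, 0.061, 0.276, 0.389,
          0.550, 0.200),
  rminHalf = c(1.34, 1.91, 1.82, 1.77, 2.02, 1.75, 1.97, 2.10, 2.25, 2.10),
  stringsAsFactors = FALSE
)

# Harmonic angle parameters by central element: theta0 in degrees,
# k in kcal/mol/rad^2.
.default_angle <- list(
  theta0 = c(C = 109.47, N = 106.7, O = 104.5, S = 92.1, P = 93.5,
             default = 109.47),
  k = c(C = 60, N = 60, O = 60, S = 60, P = 60, default = 60)
)

#' Default force-field parameter table
#'
#' @return list with components `lj` (data.frame: element, eps, rminHalf),
#'   `angle` (list: theta0 degrees, k kcal/mol/rad^2, both with a
#'   `default` entry), `coulombK` (332.0637 kcal*A/mol/e^2) and `scale14`
#'   (1-4 nonbonded scaling, default 1 = no scaling).
#' @export
defaultForcefield <- function() {
  list(lj = .default_lj, angle = .default_angle,
       coulombK = 332.0637, scale14 = 1.0)
}

#' Load a force-field parameter table from a YAML file
#'
#' The file may override any subset of the default parameters; keys are
#' `lj` (map element -> [eps, rminHalf]), `angle_theta0`, `angle_k`
#' (maps element -> value, `default` allowed), `coulombK`, `scale14`.
#'
#' @param path YAML file.
#' @return a force-field list as in [defaultForcefield()].
#' @export
loadForcefield <- function(path) {
  ff <- defaultForcefield()
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg),
                 c("lj", "angle_theta0", "angle_k", "coulombK", "scale14"))
  if (length(bad)) stop("unknown force-field keys: ", paste(bad, collapse = ", "))
  if (!is.null(cfg$lj)) {
    for (el in names(cfg$lj)) {
      v <- as.numeric(cfg$lj[[el]])
      i <- match(el, ff$lj$element)
      if (is.na(i)) {
        ff$lj <- rbind(ff$lj, data.frame(element = el, eps = v[1L],
                                         rminHalf = v[2L]))
      } else {
        ff$lj$eps[i] <- v[1L]; ff$lj$rminHalf[i] <- v[2L]
      }
    }
  }
  for (key in c("angle_theta0", "angle_k")) {
    if (!is.null(cfg[[key]])) {
      slot <- if (key == "angle_theta0") "theta0" else "k"
      for (el in names(cfg[[key]]))
        ff$angle[[slot]][el] <- as.numeric(cfg[[key]][[el]])
    }
  }
  if (!is.null(cfg$coulombK)) ff$coulombK <- as.numeric(cfg$coulombK)
  if (!is.null(cfg$scale14)) ff$scale14 <- as.numeric(cfg$scale14)
  ff
}

.lj_params <- function(elements, ff) {
  i <- match(elements, ff$lj$element)
  if (anyNA(i))
    stop("no Lennard-Jones parameters for element(s): ",
         paste(unique(elements[is.na(i)]), collapse = ", "))
  list(eps = ff$lj$eps[i], rminHalf = ff$lj$rminHalf[i])
}

.angle_param <- function(element, table) {
  v <- table[element]
  ifelse(is.na(v), table[["default"]], v)
}
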