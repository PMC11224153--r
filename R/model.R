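#' Construct a compartment specification
#'
#' One compartment of the hydraulic circuit: a linear elastic reservoir
#' (vascular) or a time-varying elastance chamber (cardiac).
#'
#' @param name compartment identifier.
#' @param kind `"vascular"` or `"cardiac"`.
#' @param E elastance in mmHg/mL (vascular compartments only).
#' @param emin,emax diastolic and end-systolic elastance in mmHg/mL
#'   (cardiac compartments only).
#' @param vu unstressed volume, mL.
#' @param height effective hydrostatic column length in cm, signed positive
#'   above heart level in the standing posture.
#' @param thoracic logical; whether the compartment sees intrathoracic
#'   pressure.
#' @param atrial logical; cardiac chambers with the late-cycle (atrial kick)
#'   activation window instead of the ventricular one.
#' @param group anatomical grouping label (cardiac / intrathoracic /
#'   upper_body / lower_body), used only for bookkeeping.
#' @param dvu_0g unstressed-volume offset (mL) applied at full microgravity
#'   fluid shift (protocol shift fraction 1).
#' @param vu_ctl,emax_ctl logicals; whether the baroreflex venous-tone and
#'   contractility effectors act on this compartment.
#' @return a one-row `data.frame` with the compartment fields.
#' @export
compartment_spec <- function(name, kind = c("vascular", "cardiac"),
                             E = NA_real_, emin = NA_real_, emax = NA_real_,
                             vu = 0, height = 0, thoracic = FALSE,
                             atrial = FALSE, group = "other", dvu_0g = 0,
                             vu_ctl = FALSE, emax_ctl = FALSE) {
  kind <- match.arg(kind)
  if (kind == "vascular") {
    if (!is.finite(E) || E <= 0) stop("vascular compartment needs E > 0")
    if (is.finite(emin) || is.finite(emax))
      stop("vascular compartments have exactly one elastance E")
  } else {
    if (!is.finite(emin) || !is.finite(emax) || emin <= 0 || emax < emin)
      stop("cardiac compartment needs Emax >= Emin > 0")
    if (is.finite(E)) stop("cardiac compartments use emin/emax, not E")
  }
  if (vu < 0) stop("unstressed volume must be >= 0")
  data.frame(name = name, group = group, kind = kind, E = E, emin = emin,
             emax = emax, vu = vu, height = height,
             thoracic = as.logical(thoracic), atrial = as.logical(atrial),
             dvu_0g = dvu_0g, vu_ctl = as.logical(vu_ctl),
             emax_ctl = as.logical(emax_ctl), stringsAsFactors = FALSE)
}

#' Assemble a closed-circuit cardiopulmonary model
#'
#' Binds the compartment table, the resistive edge list, the lymphatic
#' return edges, the global parameters and the baroreflex configuration into
#' a single validated model object.
#'
#' @param compartments data.frame of [compartment_spec()] rows.
#' @param edges data.frame with columns `from`, `to`, `R` (mmHg s/mL),
#'   `valved` (logical) and `r_ctl` (logical, baroreflex arteriolar
#'   resistance effector target).
#' @param lymph data.frame with columns `from`, `to`, `cond`
#'   (mL/(s mmHg)); one-way low-conductance return paths terminating at the
#'   superior vena cava.
#' @param globals list from [global_params()].
#' @param reflex list from [reflex_config()].
#' @param strict validate the closed-circulation invariants (every
#'   compartment has at least one inflow and one outflow and the four
#'   cardiac chambers are chained RA-RV-pulmonary-LA-LV).  Disable for toy
#'   fixtures that are deliberately open.
#' @return an object of class `cp_model`.
#' @export
build_model <- function(compartments, edges, lymph = NULL,
                        globals = global_params(), reflex = reflex_config(),
                        strict = TRUE) {
  stopifnot(is.data.frame(compartments), is.data.frame(edges))
  need <- c("name", "kind", "E", "emin", "emax", "vu", "height", "thoracic",
            "atrial", "dvu_0g", "vu_ctl", "emax_ctl")
  miss <- setdiff(need, names(compartments))
  if (length(miss))
    stop("compartment table misses column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(compartments$name)) stop("duplicate compartment names")
  vasc <- compartments$kind == "vascular"
  if (any(!is.finite(compartments$E[vasc]) | compartments$E[vasc] <= 0))
    stop("all vascular elastances must be positive")
  card <- !vasc
  if (any(!is.finite(compartments$emin[card]) | compartments$emin[card] <= 0 |
          compartments$emax[card] < compartments$emin[card]))
    stop("cardiac chambers need Emax >= Emin > 0")
  if (any(compartments$vu < 0)) stop("unstressed volumes must be >= 0")
  for (col in c("from", "to")) {
    bad <- setdiff(edges[[col]], compartments$name)
    if (length(bad)) stop("edge refers to unknown compartment: ",
                          paste(bad, collapse = ", "))
  }
  if (any(edges$R <= 0)) stop("edge resistances must be positive")
  if (is.null(lymph))
    lymph <- data.frame(from = character(), to = character(),
                        cond = numeric())
  if (nrow(lymph) && any(lymph$cond < 0))
    stop("lymphatic conductances must be >= 0")

  if (strict) {
    n_in <- table(factor(edges$to, levels = compartments$name))
    n_out <- table(factor(edges$from, levels = compartments$name))
    if (any(n_in == 0) || any(n_out == 0))
      stop("not a closed circulation: every compartment needs >= 1 inflow ",
           "and >= 1 outflow")
    chain <- list(c("ra", "rv"), c("rv", "pa"), c("pv", "la"), c("la", "lv"))
    for (lk in chain)
      if (!any(edges$from == lk[1] & edges$to == lk[2]))
        stop("cardiac chain broken: missing edge ", lk[1], " -> ", lk[2])
    if (nrow(lymph) && !all(lymph$to == "svc"))
      stop("lymphatic edges must terminate at the svc compartment")
  }

  structure(list(compartments = compartments, edges = edges, lymph = lymph,
                 globals = globals, reflex = reflex),
            class = "cp_model")
}

#' Global circulatory parameters
#'
#' @param total_blood_volume total blood volume, mL.
#' @param hr0 intrinsic heart rate, bpm (scaled at run time by the reflex
#'   chronotropic multiplier).
#' @param p_intrathoracic constant intrathoracic pressure, mmHg.
#' @param density_factor hydrostatic pressure per cm of blood column at 1 G,
#'   mmHg/cm (1.05 g/mL blood gives ~0.77).
#' @param g_level gravity as a multiple of Earth gravity (protocols override
#'   this per segment).
#' @return a list of class `cp_globals`.
#' @export
global_params <- function(total_blood_volume = 5500, hr0 = 73,
                          p_intrathoracic = -4, density_factor = 0.77,
                          g_level = 1) {
  stopifnot(total_blood_volume > 0, hr0 > 0, density_factor > 0, g_level >= 0)
  structure(list(total_blood_volume = total_blood_volume, hr0 = hr0,
                 p_intrathoracic = p_intrathoracic,
                 density_factor = density_factor, g_level = g_level),
            class = "cp_globals")
}

#' @export
print.cp_model <- function(x, ...) {
  cat("<cp_model> ", nrow(x$compartments), " compartments (",
      sum(x$compartments$kind == "cardiac"), " cardiac), ",
      nrow(x$edges), " edges, ", nrow(x$lymph), " lymphatic paths\n",
      sep = "")
  cat("  total blood volume: ", x$globals$total_blood_volume, " mL, HR0 ",
      x$globals$hr0, " bpm\n", sep = "")
  prof <- attr(x, "profile")
  if (!is.null(prof)) cat("  disease profile: ", prof, "\n", sep = "")
  invisible(x)
}

#' Read / write a compartment parameter table
#'
#' Columnar text (CSV) with one row per compartment.  Lines starting with
#' `#` are unit/documentation comments and are ignored on read.
#'
#' @param path file path.
#' @return `read_param_table` returns the compartment `data.frame`.
#' @export
read_param_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "group", "kind", "E", "emin", "emax", "vu", "height",
            "thoracic", "atrial", "dvu_0g", "vu_ctl", "emax_ctl")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("parameter table misses column(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(names(df), need)
  if (length(extra))
    stop("parameter table has unknown column(s): ",
         paste(extra, collapse = ", "))
  for (col in c("thoracic", "atrial", "vu_ctl", "emax_ctl"))
    df[[col]] <- as.logical(df[[col]])
  df
}

#' @param compartments compartment table to write.
#' @rdname read_param_table
#' @export
write_param_table <- function(compartments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# gravicor compartment parameter table",
    "# E, emin, emax: elastance, mmHg/mL | vu, dvu_0g: mL",
    "# height: hydrostatic column, cm, signed positive above heart level",
    "# thoracic/atrial/vu_ctl/emax_ctl: logical flags"), con)
  utils::write.csv(compartments, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The shipped, calibrated healthy-subject model
#'
#' Loads the baseline ("healthy astronaut") parameter set shipped with the
#' package: 21 compartments (4 cardiac chambers, 5 intrathoracic, 2
#' upper-body and 10 lower-body vascular segments), the resistive edge list,
#' global parameters and the calibrated baroreflex configuration.  The
#' table has been tuned (see [calibrate_baseline()]) so that the supine-1G
#' run and the standing-to-microgravity transition reproduce published
#' normal-subject hemodynamics.
#'
#' @return a `cp_model`, flagged as calibrated.
#' @export
default_model <- function() {
  ext <- system.file("extdata", package = "gravicor", mustWork = TRUE)
  comp <- read_param_table(file.path(ext, "params_normal.csv"))
  edges <- utils::read.csv(file.path(ext, "edges_normal.csv"),
                           comment.char = "#", stringsAsFactors = FALSE)
  edges$valved <- as.logical(edges$valved)
  edges$r_ctl <- as.logical(edges$r_ctl)
  cfg <- jsonlite::read_json(file.path(ext, "globals_normal.json"),
                             simplifyVector = TRUE)
  lymph <- data.frame(from = cfg$lymph$from, to = cfg$lymph$to,
                      cond = cfg$lymph$cond)
  gl <- global_params(total_blood_volume = cfg$globals$total_blood_volume,
                      hr0 = cfg$globals$hr0,
                      p_intrathoracic = cfg$globals$p_intrathoracic,
                      density_factor = cfg$globals$density_factor)
  rf <- do.call(reflex_config, cfg$reflex)
  m <- build_model(comp, edges, lymph, gl, rf)
  attr(m, "calibrated") <- TRUE
  m
}

# resolve a named compartment index, with a clear error
comp_index <- function(model, name) {
  i <- match(name, model$compartments$name)
  if (is.na(i)) stop("model has no compartment named '", name, "'")
  i
}

#' Distribute total blood volume over the circuit
#'
#' Initial condition used by [simulate_model()]: every compartment starts at
#' its unstressed volume plus a share of the stressed volume proportional to
#' its compliance (1/E, diastolic elastance for cardiac chambers), i.e. an
#' equal-pressure start.
#'
#' @param model a `cp_model`.
#' @param tbv total blood volume to distribute; defaults to the model's.
#' @return named numeric vector of volumes, mL.
#' @export
distribute_volumes <- function(model, tbv = model$globals$total_blood_volume) {
  comp <- model$compartments
  e_dia <- ifelse(comp$kind == "cardiac", comp$emin, comp$E)
  stressed <- tbv - sum(comp$vu)
  if (stressed <= 0)
    stop("total blood volume (", tbv, " mL) does not exceed the summed ",
         "unstressed volume (", sum(comp$vu), " mL)")
  w <- (1 / e_dia) / sum(1 / e_dia)
  setNames(comp$vu + stressed * w, comp$name)
}
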