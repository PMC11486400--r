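#' Define a measure
#'
#' A measure specification records the metadata the analysis needs to
#' interpret raw values: the unit, the therapeutic direction (whether an
#' increase or a decrease constitutes improvement), whether the measure is
#' neurophysiological or clinical, and whether it is recorded bilaterally
#' (one series per body side) or once per participant.
#'
#' @param name measure identifier, unique within a registry.
#' @param units unit string (e.g. `"ms"`, `"mV"`, `"%MSO"`, `"score"`,
#'   `"s"`, `"kg"`).
#' @param direction which change is an improvement: `"increase"` or
#'   `"decrease"`.
#' @param family `"neurophysiological"` or `"clinical"`.
#' @param bilateral logical; `TRUE` for measures assessed separately on the
#'   left and right side.
#' @return A one-row tibble.
#' @examples
#' measure_spec("rmt", "%MSO", "decrease", "neurophysiological", bilateral = TRUE)
#' @export
measure_spec <- function(name, units,
                         direction = c("decrease", "increase"),
                         family = c("neurophysiological", "clinical"),
                         bilateral = TRUE) {
  direction <- match.arg(direction)
  family <- match.arg(family)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.character(units), length(units) == 1L,
            is.logical(bilateral), length(bilateral) == 1L)
  tibble::tibble(name = name, units = units, direction = direction,
                 family = family, bilateral = bilateral)
}

#' Default measure registry
#'
#' The measures of a TMS + clinical assessment battery for people with
#' relapsing-remitting multiple sclerosis, with their therapeutic
#' directions. A decrease is an improvement for the temporal conduction
#' measures (CMCT, MEP latency), for the resting motor threshold (a lower
#' threshold means higher excitability), for a timed walking test, and for
#' a fatigue questionnaire; an increase is an improvement for MEP
#' amplitude, balance, arm function, strength and processing speed.
#'
#' The registry is plain data: override or extend it by binding rows, or
#' load a replacement from YAML with [registry_from_yaml()].
#'
#' @return Tibble with columns `name`, `units`, `direction`, `family`,
#'   `bilateral`.
#' @export
default_measure_registry <- function() {
  reg <- dplyr::bind_rows(
    measure_spec("cmct",          "ms",    "decrease", "neurophysiological", TRUE),
    measure_spec("mep_amplitude", "mV",    "increase", "neurophysiological", TRUE),
    measure_spec("mep_latency",   "ms",    "decrease", "neurophysiological", TRUE),
    measure_spec("rmt",           "%MSO",  "decrease", "neurophysiological", TRUE),
    measure_spec("minibest",      "score", "increase", "clinical", FALSE),
    measure_spec("six_spot_step", "s",     "decrease", "clinical", FALSE),
    measure_spec("arat",          "score", "increase", "clinical", TRUE),
    measure_spec("strength",      "kg",    "increase", "clinical", TRUE),
    measure_spec("sdmt",          "score", "increase", "clinical", FALSE),
    measure_spec("mfis",          "score", "decrease", "clinical", FALSE)
  )
  validate_registry(reg)
  reg
}

#' @rdname default_measure_registry
#' @param registry a registry tibble.
#' @export
validate_registry <- function(registry) {
  needed <- c("name", "units", "direction", "family", "bilateral")
  miss <- setdiff(needed, names(registry))
  if (length(miss) > 0) stop("registry is missing column(s): ",
                             paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(registry$name)) {
    stop("duplicate measure name(s) in registry: ",
         paste(unique(registry$name[duplicated(registry$name)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(registry$direction %in% c("increase", "decrease"))) {
    stop("registry direction must be 'increase' or 'decrease'", call. = FALSE)
  }
  invisible(registry)
}

#' Look up one measure in a registry
#'
#' @param registry registry tibble (see [default_measure_registry()]).
#' @param name measure name.
#' @return One-row tibble.
#' @export
get_measure_spec <- function(registry, name) {
  hit <- registry[registry$name == name, , drop = FALSE]
  if (nrow(hit) != 1L) stop("measure not found in registry: ", name, call. = FALSE)
  hit
}

#' Load a measure registry from YAML
#'
#' Expects a top-level `measures:` list whose entries carry `name`,
#' `units`, `direction`, `family` and `bilateral` fields; entries replace
#' same-named measures of the default registry and new names are appended.
#'
#' @param path YAML file path.
#' @param base registry to override; defaults to [default_measure_registry()].
#' @return Registry tibble.
#' @export
registry_from_yaml <- function(path, base = default_measure_registry()) {
  cfg <- yaml::read_yaml(path)
  entries <- cfg$measures
  if (is.null(entries)) stop("YAML registry must have a 'measures' key", call. = FALSE)
  extra <- dplyr::bind_rows(lapply(entries, function(e) {
    measure_spec(e$name, e$units, e$direction, e$family,
                 bilateral = isTRUE(e$bilateral))
  }))
  reg <- dplyr::bind_rows(base[!base$name %in% extra$name, ], extra)
  validate_registry(reg)
  reg
}
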