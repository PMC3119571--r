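# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed conditions so callers/tests can distinguish failure categories
# (usage/config vs parse vs lookup vs numerical).
erbb_abort <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "erbb_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

abort_usage   <- function(msg, ...) erbb_abort("erbb_usage_error", msg, ...)
abort_parse   <- function(msg, ...) erbb_abort("erbb_parse_error", msg, ...)
abort_lookup  <- function(msg, ...) erbb_abort("erbb_lookup_error", msg, ...)
abort_shape   <- function(msg, ...) erbb_abort("erbb_shape_error", msg, ...)
abort_schema  <- function(msg, ...) erbb_abort("erbb_schema_error", msg, ...)
abort_range   <- function(msg, ...) erbb_abort("erbb_range_error", msg, ...)
abort_input   <- function(msg, ...) erbb_abort("erbb_input_error", msg, ...)
abort_config  <- function(msg, ...) erbb_abort("erbb_config_error", msg, ...)
abort_geometry <- function(msg, ...) erbb_abort("erbb_geometry_error", msg, ...)
abort_stat     <- function(msg, ...) erbb_abort("erbb_statistics_error", msg, ...)
abort_placement <- function(msg, ...) erbb_abort("erbb_placement_error", msg, ...)
abort_integration <- function(msg, ...) erbb_abort("erbb_integration_error", msg, ...)

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "erbbscale")
  if (!nzchar(p)) erbb_abort("erbb_internal_error", "packaged data file '%s' not found", file)
  p
}

# Residue names recognised as water across common force-field conventions.
WATER_RESNAMES <- c("HOH", "WAT", "TIP3", "SOL")

is_water_resname <- function(x) toupper(x) %in% WATER_RESNAMES

# squared Euclidean distances between rows of a (n x 3) and a single point p
dist2_to_point <- function(a, p) {
  (a[, 1] - p[1])^2 + (a[, 2] - p[2])^2 + (a[, 3] - p[3])^2
}
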