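# Scenario file format
# --------------------
# Flat, YAML-compatible key-value text. Each uncertain input is a flow
# sequence [point, low, high, family]; strategy fields are namespaced with
# "intervention." / "comparator." prefixes. Example:
#
#   label: duration6
#   horizon_months: 6
#   wtp_grid: [0, 100, ..., 5000]
#   intervention.name: liraglutide
#   intervention.hba1c_reduction: [1.48, 1.38, 1.58, beta]
#   ...
#   shared.gi_event_cost: [1113, 890, 1335, normal]
#
# Numbers are written with enough digits that load_scenario(write_scenario(x))
# reproduces every field bit-exactly.

.scenario_keys <- function() {
  strat <- function(p) paste0(p, ".", c("name", names(.STRATEGY_FIELDS)))
  c("label", "horizon_months", "wtp_grid",
    strat("intervention"), strat("comparator"), "shared.gi_event_cost")
}

# Shortest decimal string that parses back to exactly x.
.num_str <- function(x) {
  if (x == round(x) && abs(x) < 1e15) return(format(x, scientific = FALSE))
  s <- trimws(formatC(x, digits = 15, format = "g"))
  if (as.numeric(s) != x) s <- trimws(formatC(x, digits = 17, format = "g"))
  s
}

.input_str <- function(u) {
  sprintf("[%s, %s, %s, %s]",
          .num_str(u$point), .num_str(u$low), .num_str(u$high), u$family)
}

#' Write a scenario file
#'
#' Serialises a scenario to the package's flat key-value (YAML-compatible)
#' format. The written file round-trips: [load_scenario()] on the result
#' reproduces every field of `x` bit-exactly.
#'
#' @param x A [scenario()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(x, path) {
  validate_scenario(x)
  lines <- c(
    paste0("label: ", x$label),
    paste0("horizon_months: ", x$shared$horizon_months),
    paste0("wtp_grid: [",
           paste(vapply(x$shared$wtp_grid, .num_str, ""), collapse = ", "),
           "]"))
  for (role in c("intervention", "comparator")) {
    s <- x[[role]]
    lines <- c(lines, paste0(role, ".name: ", s$name))
    for (f in names(.STRATEGY_FIELDS)) {
      lines <- c(lines, paste0(role, ".", f, ": ", .input_str(s[[f]])))
    }
  }
  lines <- c(lines,
             paste0("shared.gi_event_cost: ", .input_str(x$shared$gi_event_cost)))
  writeLines(lines, path)
  invisible(path)
}

.parse_input <- function(v, key) {
  if (!is.list(v)) v <- as.list(v)
  if (length(v) != 4L) {
    stop("scenario format error at '", key,
         "': expected [point, low, high, family]", call. = FALSE)
  }
  num <- suppressWarnings(vapply(v[1:3], function(z) as.numeric(z)[1], 0))
  if (any(is.na(num))) {
    stop("scenario format error at '", key,
         "': point/low/high must be numeric", call. = FALSE)
  }
  fam <- as.character(v[[4]])
  if (!(fam %in% c("beta", "normal", "fixed"))) {
    stop("scenario format error at '", key,
         "': unknown family '", fam, "'", call. = FALSE)
  }
  x <- structure(list(point = num[[1]], low = num[[2]], high = num[[3]],
                      family = fam), class = "uncertain_input")
  validate_uncertain_input(x, key)
  x
}

#' Read and validate a scenario file
#'
#' Parses the flat key-value scenario format (see [write_scenario()]) and
#' returns a fully validated [scenario()]. Unknown or missing keys raise a
#' format error naming the key; domain violations raise a validation error
#' naming the field and rule.
#'
#' @param path Path to a scenario file.
#' @return A validated [scenario()].
#' @examples
#' path <- system.file("extdata", "duration6.yaml", package = "glp1ce")
#' scn <- load_scenario(path)
#' scn$intervention$hba1c_reduction$point # 1.48
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path, call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("scenario format error: cannot parse '", path, "': ",
         conditionMessage(e), call. = FALSE)
  })
  keys <- .scenario_keys()
  unknown <- setdiff(names(raw), keys)
  if (length(unknown)) {
    stop("scenario format error: unknown key '", unknown[[1]], "'",
         call. = FALSE)
  }
  missing <- setdiff(keys, names(raw))
  if (length(missing)) {
    stop("scenario format error: missing key '", missing[[1]], "'",
         call. = FALSE)
  }
  read_strategy <- function(role) {
    args <- list(name = as.character(raw[[paste0(role, ".name")]]))
    for (f in names(.STRATEGY_FIELDS)) {
      key <- paste0(role, ".", f)
      args[[f]] <- .parse_input(raw[[key]], key)
    }
    do.call(strategy_inputs, args)
  }
  shared <- shared_inputs(
    gi_event_cost  = .parse_input(raw[["shared.gi_event_cost"]],
                                  "shared.gi_event_cost"),
    horizon_months = raw[["horizon_months"]],
    wtp_grid       = unlist(raw[["wtp_grid"]]))
  scenario(read_strategy("intervention"), read_strategy("comparator"),
           shared, label = as.character(raw[["label"]]))
}
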