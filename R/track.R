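# Run-time instrumentation: wrapping data-processing functions so each call
# in the activated scope contributes one execution record to the session
# history. The wrapper is transparent: return values are identical to the
# unwrapped call, and any capture failure degrades with a warning instead of
# altering the user's computation.

#' Wrap a function for provenance tracking
#'
#' Returns a wrapper with identical call behavior. While a capture session
#' is active (see [activate()]), each call appends one execution record
#' with: descriptors of the arguments declared as inputs, SHA-256 file
#' descriptors for file inputs/outputs (hashed before/after the call,
#' respectively), all remaining arguments as parameters (declared defaults
#' are resolved and recorded even when not written at the call site),
#' positional descriptors of the returned value(s), container-access
#' relationships found at the call site, start/end timestamps, and the
#' session-wide execution order. When no session is active the wrapper is a
#' pure pass-through.
#'
#' Multiple outputs are expressed as a plain unclassed list: its elements
#' are enumerated positionally as separate outputs. A `NULL` return is
#' described with the shared null-object identifier. An argument object
#' that the call mutates (content hash changed afterwards) is additionally
#' recorded as an output.
#'
#' @param fun function to wrap.
#' @param inputs character vector of argument names holding data-object
#'   inputs.
#' @param file_inputs,file_outputs argument names holding path strings of
#'   files read / written by the function.
#' @param name recorded function name; defaults to the expression passed as
#'   `fun`.
#' @return the wrapped function.
#' @examples
#' sq <- track(function(x) x^2, inputs = "x", name = "sq")
#' sq(4)  # == 16, tracked only while a session is active
#' @export
track <- function(fun, inputs = NULL, file_inputs = NULL,
                  file_outputs = NULL, name = NULL) {
  stopifnot(is.function(fun))
  if (is.null(name)) {
    name <- paste(deparse(substitute(fun)), collapse = "")
    if (!grepl("^[[:alnum:]._]+$", name)) name <- "anonymous"
  }
  inputs <- as.character(inputs %||% character())
  file_inputs <- as.character(file_inputs %||% character())
  file_outputs <- as.character(file_outputs %||% character())

  roles <- c(inputs, file_inputs, file_outputs)
  if (anyDuplicated(roles)) {
    stop("input/file role sets must be disjoint", call. = FALSE)
  }
  match_def <- if (is.primitive(fun)) args(fun) else fun
  fml_names <- names(formals(match_def))
  if (!is.null(fml_names) && !("..." %in% fml_names)) {
    unknown <- setdiff(roles, fml_names)
    if (length(unknown) > 0L) {
      stop("role name(s) not among declared arguments of ", name, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  info <- function_info(fun, name)

  wrapper <- function(...) {
    cl <- sys.call()
    caller <- parent.frame()
    if (!session_active()) {
      cl2 <- cl
      cl2[[1L]] <- fun
      return(eval(cl2, caller))
    }
    session <- current_session(finished = FALSE)
    settings <- settings_env()

    bound <- bind_arguments(fun, match_def, cl, caller)
    if (is.null(bound)) {
      # argument binding/evaluation failed: run the call untouched
      warning("provenance capture skipped for a call to ", name,
              " (argument binding failed)", call. = FALSE)
      cl2 <- cl
      cl2[[1L]] <- fun
      return(eval(cl2, caller))
    }

    pre <- describe_roles_pre(bound, inputs, file_inputs, settings)
    t0 <- settings$clock()
    result <- do.call(fun, bound$call_values)
    t1 <- settings$clock()

    tryCatch(
      record_execution(session, info, bound, pre, result,
                       inputs, file_inputs, file_outputs,
                       t0, t1, cl, caller, settings),
      error = function(e) {
        warning("provenance record dropped for a call to ", name, ": ",
                conditionMessage(e), call. = FALSE)
      })
    result
  }
  attr(wrapper, "provtrace") <- list(name = name, inputs = inputs,
                                     file_inputs = file_inputs,
                                     file_outputs = file_outputs)
  wrapper
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Resolve the call against the declared signature: evaluate supplied
# arguments once in the caller's frame and resolve declared defaults for
# the rest (so defaulted parameters are recorded too). Returns NULL when
# binding is impossible (e.g. dots forwarding the wrapper cannot see).
bind_arguments <- function(fun, match_def, cl, caller) {
  matched <- tryCatch(
    match.call(definition = match_def %||% fun, call = cl,
               expand.dots = TRUE),
    error = function(e) NULL)
  if (is.null(matched)) return(NULL)
  arg_exprs <- as.list(matched)[-1L]
  call_names <- names(arg_exprs) %||% rep("", length(arg_exprs))
  # recording labels: positional dots arguments get synthetic names
  labels <- call_names
  labels[labels == ""] <- paste0("..", which(labels == ""))

  values <- vector("list", length(arg_exprs))
  for (i in seq_along(arg_exprs)) {
    v <- tryCatch(list(eval(arg_exprs[[i]], caller)), error = function(e) NULL)
    if (is.null(v)) return(NULL)
    values[i] <- v
  }
  call_values <- values
  names(call_values) <- call_names    # "" names stay positional for the call
  names(values) <- labels
  names(arg_exprs) <- labels

  defaults <- list()
  fmls <- formals(match_def %||% fun)
  named_vals <- values[call_names != ""]
  default_env <- list2env(if (length(named_vals)) named_vals else list(),
                          parent = environment(fun) %||% baseenv())
  for (nm in setdiff(names(fmls), c(names(values), "..."))) {
    d <- fmls[[nm]]
    if (identical(d, quote(expr = ))) next   # no default declared
    defaults[[nm]] <- tryCatch(eval(d, default_env),
                               error = function(e) {
                                 paste(deparse(d), collapse = " ")
                               })
  }
  list(values = values, call_values = call_values, defaults = defaults,
       exprs = arg_exprs)
}

# Inputs are described before the call (files read by the function are
# hashed in the state the function sees them).
describe_roles_pre <- function(bound, inputs, file_inputs, settings) {
  all_args <- c(bound$values, bound$defaults)
  ins <- list()
  for (nm in intersect(inputs, names(all_args))) {
    ins[[nm]] <- describe_or_placeholder(all_args[[nm]], settings)
  }
  for (nm in intersect(file_inputs, names(all_args))) {
    ins[[nm]] <- tryCatch(describe_file(all_args[[nm]]),
                          error = function(e) placeholder_descriptor(e))
  }
  ins
}

describe_or_placeholder <- function(value, settings) {
  tryCatch(describe_object(value, settings),
           error = function(e) placeholder_descriptor(e, value))
}

placeholder_descriptor <- function(e, value = NULL) {
  warning("object description degraded: ", conditionMessage(e),
          call. = FALSE)
  structure(
    list(type_name = if (is.null(value)) "unknown" else class(value)[1L],
         module_path = "R",
         content_hash = digest::digest(conditionMessage(e), algo = "sha1"),
         hash_method = "builtin_hash",
         memory_address = "0x0",
         attributes = list(description_error = conditionMessage(e)),
         annotations = list()),
    class = "provtrace_object")
}

#' @keywords internal
function_info <- function(fun, name) {
  if (is.primitive(fun)) {
    return(list(name = name, module_path = "base",
                version = as.character(getRversion())))
  }
  env <- environment(fun)
  env_name <- if (!is.null(env)) environmentName(topenv(env)) else ""
  if (nzchar(env_name) && env_name != "R_GlobalEnv" &&
      !is.null(tryCatch(getNamespace(env_name), error = function(e) NULL))) {
    ver <- tryCatch(as.character(packageVersion(env_name)),
                    error = function(e) "NA")
    return(list(name = name, module_path = env_name, version = ver))
  }
  # functions defined in the tracked script itself carry no version
  list(name = name, module_path = "__main__", version = "NA")
}

dotted_name <- function(info) paste(info$module_path, info$name, sep = ".")

# --- execution records ------------------------------------------------------

iso_time <- function(t) {
  paste0(format(t, "%Y-%m-%dT%H:%M:%OS6", tz = "UTC"), "Z")
}

#' Build and append one execution record
#'
#' Internal worker behind the [track()] wrapper: increments the session
#' counter, describes outputs (and re-describes inputs to detect in-place
#' mutation), snapshots parameters, analyzes the call-site expression for
#' container accesses, and appends the finished record to the history.
#'
#' @keywords internal
record_execution <- function(session, info, bound, pre, result,
                             inputs, file_inputs, file_outputs,
                             t0, t1, cl, caller, settings) {
  all_args <- c(bound$values, bound$defaults)

  outputs <- list()
  if (is.list(result) && !is.object(result)) {
    for (el in result) {
      outputs[[length(outputs) + 1L]] <- describe_or_placeholder(el, settings)
    }
  } else {
    outputs[[1L]] <- describe_or_placeholder(result, settings)
  }
  for (nm in intersect(file_outputs, names(all_args))) {
    outputs[[length(outputs) + 1L]] <-
      tryCatch(describe_file(all_args[[nm]]),
               error = function(e) placeholder_descriptor(e))
  }
  # in-place mutation: an object input whose content hash changed during the
  # call is also an output of the call
  for (nm in intersect(inputs, names(all_args))) {
    before <- pre[[nm]]
    if (is.null(before) || !inherits(before, "provtrace_object")) next
    after <- describe_or_placeholder(all_args[[nm]], settings)
    if (!identical(after$content_hash, before$content_hash)) {
      outputs[[length(outputs) + 1L]] <- after
    }
  }

  param_names <- setdiff(names(all_args), c(inputs, file_inputs, file_outputs))
  parameters <- lapply(all_args[param_names], snapshot_value,
                       settings = settings)

  memberships <- analyze_call_site(bound$exprs[intersect(inputs,
                                                         names(bound$exprs))],
                                   caller, settings)

  session$counter <- session$counter + 1L
  record <- list(
    execution_id = settings$id_source(),
    fun = info,
    inputs = pre,
    parameters = parameters,
    outputs = outputs,
    memberships = memberships,
    order = session$counter,
    time_start = iso_time(t0),
    time_end = iso_time(t1),
    code_statement = resolve_statement(cl, session))
  class(record) <- "provtrace_record"
  session$history[[session$counter]] <- record
  invisible(record)
}

# --- call-site analysis -----------------------------------------------------

# Decompose an argument expression into a chain of container accesses
# (attribute via `$`/`@`, index via `[[`, slice via `[`), innermost first.
# Returns NULL unless the chain bottoms out in a plain variable, so that
# re-evaluating prefixes in the live frame is side-effect free.
decompose_access_chain <- function(expr) {
  hops <- list()
  e <- expr
  while (is.call(e) && length(e) >= 2L) {
    op <- deparse(e[[1L]], nlines = 1L)
    if (op %in% c("$", "@")) {
      acc <- if (is.name(e[[3L]])) as.character(e[[3L]]) else
        deparse(e[[3L]], nlines = 1L)
      hops <- c(list(list(container_expr = e[[2L]], element_expr = e,
                          relation = "attribute", accessor = acc)), hops)
      e <- e[[2L]]
    } else if (op == "[[" && length(e) == 3L) {
      idx <- e[[3L]]
      acc <- if (is.character(idx)) idx else
        paste(deparse(idx), collapse = "")
      hops <- c(list(list(container_expr = e[[2L]], element_expr = e,
                          relation = "index", accessor = acc,
                          accessor_expr = if (!is.character(idx) &&
                                              !is.numeric(idx)) idx)), hops)
      e <- e[[2L]]
    } else if (op == "[") {
      idx_parts <- as.list(e)[-(1:2)]
      acc <- paste(vapply(idx_parts, function(p) {
        if (identical(p, quote(expr = ))) "" else
          paste(deparse(p), collapse = "")
      }, character(1L)), collapse = ",")
      hops <- c(list(list(container_expr = e[[2L]], element_expr = e,
                          relation = "slice", accessor = acc)), hops)
      e <- e[[2L]]
    } else {
      return(NULL)
    }
  }
  if (!is.name(e)) return(NULL)
  hops
}

#' Analyze a call site for container accesses
#'
#' For every input-argument expression that reaches the call through
#' attribute access, indexing, or slicing of a container (possibly
#' chained, e.g. `block$segments[[1]]`), emits one membership record
#' per hop, resolving the intermediate objects from the live calling frame.
#' Expressions that are not pure access chains (or dynamically built calls
#' that cannot be resolved) contribute no memberships; the call is still
#' recorded.
#'
#' @param arg_exprs named list of argument expressions (input roles only).
#' @param caller frame in which the call was made.
#' @param settings capture settings.
#' @return list of membership records, each with fields `container`,
#'   `element` (object descriptors), `relation` (`"attribute"`,
#'   `"index"` or `"slice"`), and the `accessor` string.
#' @keywords internal
analyze_call_site <- function(arg_exprs, caller,
                              settings = settings_env()) {
  memberships <- list()
  for (expr in arg_exprs) {
    hops <- decompose_access_chain(expr)
    if (is.null(hops) || length(hops) == 0L) next
    for (hop in hops) {
      vals <- tryCatch(
        list(container = eval(hop$container_expr, caller),
             element = eval(hop$element_expr, caller)),
        error = function(e) NULL)
      if (is.null(vals)) next
      accessor <- hop$accessor
      # indexes held in variables are resolved to their runtime value
      if (!is.null(hop$accessor_expr)) {
        iv <- tryCatch(eval(hop$accessor_expr, caller),
                       error = function(e) NULL)
        if (is.atomic(iv) && length(iv) == 1L && !is.na(iv)) {
          accessor <- as.character(iv)
        }
      }
      memberships[[length(memberships) + 1L]] <- list(
        container = describe_or_placeholder(vals$container, settings),
        element = describe_or_placeholder(vals$element, settings),
        relation = hop$relation,
        accessor = accessor)
    }
  }
  memberships
}
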