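#' Build contrast rules
#'
#' \code{setRule} matches a categorical phenotype value against a value
#' set; \code{rangeRule} matches a numeric value against an interval.
#' Values are compared as character for set rules and as numeric for
#' range rules.
#'
#' @param values vector of admissible values (set rule).
#' @param min,max interval bounds (range rule); \code{-Inf}/\code{Inf}
#'   for one-sided intervals.
#' @param includeMin,includeMax are the bounds part of the interval?
#' @return A rule list consumed by \code{\link{contrastSpec}}.
#' @examples
#' rangeRule(min = 25, includeMin = FALSE)   # strictly greater than 25
#' setRule(c(1, 2))
#' @export
setRule <- function(values) list(type = "set", values = as.character(values))

#' @rdname setRule
#' @export
rangeRule <- function(min = -Inf, max = Inf, includeMin = TRUE,
                      includeMax = TRUE) {
  list(type = "range", min = min, max = max,
       includeMin = includeMin, includeMax = includeMax)
}

#' Construct a ContrastSpec
#'
#' @param name contrast name.
#' @param variable phenotype column name.
#' @param class1,class2 rules built by \code{\link{setRule}} or
#'   \code{\link{rangeRule}}; they must select disjoint value sets.
#' @param excludeIfTrue optional phenotype column; samples where it is
#'   true are excluded from the contrast.
#' @return A \linkS4class{ContrastSpec}.
#' @export
contrastSpec <- function(name, variable, class1, class2,
                         excludeIfTrue = NA_character_) {
  new("ContrastSpec", name = name, variable = variable,
      class1Rule = class1, class2Rule = class2,
      excludeIfTrue = excludeIfTrue)
}

#' Built-in clinical contrast registry
#'
#' The contrasts used throughout: histological grade (1&2 vs 3, and 1 vs
#' 2), tumor size (>25 mm vs <20 mm, 20-25 mm excluded), ER status
#' (positive vs negative), five-year relapse vs relapse-free (samples
#' censored before five years are excluded when a
#' \code{censored_before_5y} column is present), tumor vs control tissue,
#' age (<55 vs >=55; the boundary age 55 is assigned to the second class
#' rather than discarded), smoker vs non-smoker, and the simulated
#' \code{group} contrast.
#'
#' Expected phenotype columns: \code{grade} (1/2/3), \code{size_mm}
#' (numeric), \code{er_status} (pos/neg), \code{relapse5y}
#' (relapse/free), \code{tissue} (tumor/control), \code{age} (numeric),
#' \code{smoking} (smoker/nonsmoker), \code{group} (class1/class2).
#'
#' @param name optional single contrast name to retrieve.
#' @return A named list of \linkS4class{ContrastSpec} objects, or one
#'   spec when \code{name} is given.
#' @export
builtinContrasts <- function(name = NULL) {
  reg <- list(
    grade12_vs_3 = contrastSpec("grade12_vs_3", "grade",
                                setRule(c("1", "2")), setRule("3")),
    grade1_vs_2 = contrastSpec("grade1_vs_2", "grade",
                               setRule("1"), setRule("2")),
    size_gt25_vs_lt20 = contrastSpec("size_gt25_vs_lt20", "size_mm",
                                     rangeRule(min = 25, includeMin = FALSE),
                                     rangeRule(max = 20, includeMax = FALSE)),
    er_pos_vs_neg = contrastSpec("er_pos_vs_neg", "er_status",
                                 setRule(c("pos", "positive")),
                                 setRule(c("neg", "negative"))),
    relapse5y_vs_free = contrastSpec("relapse5y_vs_free", "relapse5y",
                                     setRule("relapse"), setRule("free"),
                                     excludeIfTrue = "censored_before_5y"),
    tumor_vs_control = contrastSpec("tumor_vs_control", "tissue",
                                    setRule("tumor"), setRule("control")),
    age_lt55_vs_ge55 = contrastSpec("age_lt55_vs_ge55", "age",
                                    rangeRule(max = 55, includeMax = FALSE),
                                    rangeRule(min = 55, includeMin = TRUE)),
    smoker_vs_nonsmoker = contrastSpec("smoker_vs_nonsmoker", "smoking",
                                       setRule("smoker"),
                                       setRule(c("nonsmoker", "non-smoker"))),
    group_c1_vs_c2 = contrastSpec("group_c1_vs_c2", "group",
                                  setRule("class1"), setRule("class2"))
  )
  if (is.null(name)) return(reg)
  if (!name %in% names(reg))
    stop("unknown contrast '", name, "'; known: ",
         paste(names(reg), collapse = ", "))
  reg[[name]]
}

#' Load a contrast registry from YAML
#'
#' Reads a YAML config mapping contrast names to a variable and two class
#' rules. Each entry has a \code{variable} field and \code{class1}/
#' \code{class2} fields that are either \code{set: [...]} or an interval
#' \code{min}/\code{max} with optional \code{include_min}/
#' \code{include_max}; an optional \code{exclude_if_true} names a column
#' of samples to drop.
#'
#' @param path path to the YAML file.
#' @return A named list of \linkS4class{ContrastSpec} objects.
#' @export
loadContrastRegistry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  parseRule <- function(r) {
    if (!is.null(r$set)) return(setRule(unlist(r$set)))
    rangeRule(min = if (is.null(r$min)) -Inf else r$min,
              max = if (is.null(r$max)) Inf else r$max,
              includeMin = !isFALSE(r$include_min),
              includeMax = !isFALSE(r$include_max))
  }
  out <- lapply(names(cfg), function(nm) {
    e <- cfg[[nm]]
    contrastSpec(nm, e$variable, parseRule(e$class1), parseRule(e$class2),
                 excludeIfTrue = if (is.null(e$exclude_if_true))
                   NA_character_ else e$exclude_if_true)
  })
  stats::setNames(out, names(cfg))
}

.matchRule <- function(values, rule) {
  if (rule$type == "set") {
    as.character(values) %in% rule$values
  } else {
    v <- suppressWarnings(as.numeric(values))
    lo <- if (rule$includeMin) v >= rule$min else v > rule$min
    hi <- if (rule$includeMax) v <= rule$max else v < rule$max
    ok <- lo & hi
    ok[is.na(ok)] <- FALSE
    ok
  }
}

#' Binarize a phenotype variable into a two-class contrast
#'
#' Applies a \linkS4class{ContrastSpec} to a study's phenotype table.
#' Samples with a missing value, or matching neither class rule, are
#' excluded from the contrast (never assigned); a sample matching both
#' rules is an error. Both resulting classes must contain at least two
#' samples.
#'
#' @param study an \linkS4class{ExpressionStudy}.
#' @param spec a \linkS4class{ContrastSpec}, or the name of a built-in
#'   contrast (see \code{\link{builtinContrasts}}).
#' @return A \linkS4class{BinaryContrast}.
#' @export
binarizePhenotype <- function(study, spec) {
  stopifnot(is(study, "ExpressionStudy"))
  if (is.character(spec)) spec <- builtinContrasts(spec)
  stopifnot(is(spec, "ContrastSpec"))
  ph <- phenoTable(study)
  if (!spec@variable %in% colnames(ph))
    stop("phenotype variable '", spec@variable, "' not present in study '",
         studyId(study), "'")
  values <- ph[[spec@variable]]
  keep <- !is.na(values)
  if (!is.na(spec@excludeIfTrue) && spec@excludeIfTrue %in% colnames(ph)) {
    cens <- ph[[spec@excludeIfTrue]]
    censored <- !is.na(cens) &
      (as.character(cens) %in% c("TRUE", "true", "yes", "1"))
    keep <- keep & !censored
  }
  in1 <- .matchRule(values, spec@class1Rule) & keep
  in2 <- .matchRule(values, spec@class2Rule) & keep
  if (any(in1 & in2))
    stop("contrast '", spec@name, "': rules are not disjoint on sample(s) ",
         paste(utils::head(colnames(study)[in1 & in2], 3L), collapse = ", "))
  sel <- in1 | in2
  if (sum(in1) < 2L)
    stop("contrast '", spec@name, "': class1 has ", sum(in1),
         " sample(s), need at least 2")
  if (sum(in2) < 2L)
    stop("contrast '", spec@name, "': class2 has ", sum(in2),
         " sample(s), need at least 2")
  labels <- factor(ifelse(in1[sel], "class1", "class2"),
                   levels = c("class1", "class2"))
  new("BinaryContrast", name = spec@name,
      sampleIds = colnames(study)[sel], labels = labels)
}
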