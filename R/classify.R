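# Drug-class mapping and combination-product resolution.
#
# Chemicals are mapped to one of six antidiabetic classes (plus "other")
# through a curated table; matching is a deterministic normalisation
# cascade, not fuzzy string distance, so results are reproducible.

# salt / hydrate suffix words stripped during full normalisation
SALT_WORDS <- c(
  "hydrochloride", "hcl", "maleate", "sodium", "calcium", "potassium",
  "phosphate", "tartrate", "benzoate", "acetate", "anhydrous",
  "monohydrate", "hemihydrate", "propanediol"
)

norm_basic <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

norm_full <- function(x) {
  x <- norm_basic(x)
  x <- gsub("[[:punct:]]+", " ", x)
  # drop salt/hydrate tokens
  x <- vapply(strsplit(x, " ", fixed = TRUE), function(tok) {
    paste(tok[!tok %in% SALT_WORDS], collapse = " ")
  }, character(1))
  trimws(gsub("[[:space:]]+", " ", x))
}

#' Read a drug class map
#'
#' Reads the chemical-to-class table used to classify antidiabetic drugs.
#' The file has columns `chemical,class,synonym_of`: canonical rows carry a
#' class label and an empty `synonym_of`; synonym rows carry an empty class
#' and name the canonical chemical they stand for. The shipped default map
#' covers the standard BNF 6.1.2 agents.
#'
#' @param path path to the map CSV; defaults to the map shipped with the
#'   package.
#' @return a `drug_class_map` object.
#' @export
#' @examples
#' cm <- read_class_map()
#' classify_chemical("Metformin Hydrochloride", cm)
read_class_map <- function(path = default_class_map_path()) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    chemical = readr::col_character(),
    class = readr::col_character(),
    synonym_of = readr::col_character()
  ))
  required <- c("chemical", "class", "synonym_of")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("class map is missing required column(s): ", paste(missing, collapse = ", "))
  }
  is_canonical <- is.na(raw$synonym_of) | raw$synonym_of == ""
  canon <- raw[is_canonical, ]
  syn <- raw[!is_canonical, ]

  if (any(is.na(canon$class) | !canon$class %in% ALL_CLASSES)) {
    bad <- canon$chemical[is.na(canon$class) | !canon$class %in% ALL_CLASSES]
    stop("canonical chemical(s) with missing/unknown class: ", paste(bad, collapse = ", "))
  }
  key <- norm_basic(canon$chemical)
  if (anyDuplicated(key)) {
    stop("duplicate canonical chemical(s): ", paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  entries <- setNames(canon$class, key)

  syn_target <- norm_basic(syn$synonym_of)
  unknown <- setdiff(syn_target, names(entries))
  if (length(unknown) > 0) {
    stop("synonym(s) point at unknown canonical chemical: ", paste(unknown, collapse = ", "))
  }

  # alias -> canonical lookup at both normalisation levels
  alias <- c(setNames(names(entries), names(entries)), setNames(syn_target, norm_basic(syn$chemical)))
  full_keys <- norm_full(names(alias))
  alias_full <- setNames(unname(alias), full_keys)
  conflicts <- tapply(alias_full, names(alias_full), function(v) length(unique(v)))
  if (any(conflicts > 1)) {
    stop("normalisation collapses distinct chemicals onto one key: ",
         paste(names(conflicts)[conflicts > 1], collapse = ", "))
  }
  alias_full <- alias_full[!duplicated(names(alias_full))]

  structure(
    list(entries = entries, alias_basic = alias, alias_full = alias_full, source = path),
    class = "drug_class_map"
  )
}

#' @export
print.drug_class_map <- function(x, ...) {
  cat("<drug_class_map> ", length(x$entries), " canonical chemicals, ",
      length(x$alias_basic) - length(x$entries), " synonyms\n", sep = "")
  tab <- table(factor(x$entries, levels = ALL_CLASSES))
  cat(paste0("  ", names(tab), ": ", as.integer(tab), collapse = "\n"), "\n", sep = "")
  invisible(x)
}

#' Path of the shipped drug class map
#' @return file path of the default `drug_class_map.csv`.
#' @export
default_class_map_path <- function() {
  system.file("extdata", "drug_class_map.csv", package = "rxlines", mustWork = TRUE)
}

#' Classify a chemical name into an antidiabetic drug class
#'
#' Exact (case- and whitespace-insensitive) matching is preferred; failing
#' that, a normalised match is attempted after stripping punctuation and
#' salt/hydrate suffixes (e.g. "hydrochloride"). Names that still do not
#' match are unresolved and returned as `NA`.
#'
#' @param name character vector of chemical names.
#' @param class_map a `drug_class_map` (see [read_class_map()]).
#' @return character vector of class labels, `NA` where unresolved.
#' @export
#' @examples
#' cm <- read_class_map()
#' classify_chemical(c("metformin", "Pioglitazone Hydrochloride", "banana extract"), cm)
classify_chemical <- function(name, class_map) {
  stopifnot(inherits(class_map, "drug_class_map"))
  if (length(class_map$entries) == 0) stop("class map is empty")
  canon <- unname(class_map$alias_basic[norm_basic(name)])
  miss <- is.na(canon)
  if (any(miss)) {
    canon[miss] <- unname(class_map$alias_full[norm_full(name[miss])])
  }
  unname(class_map$entries[canon])
}

#' Split a product name into constituent chemicals
#'
#' Combination products appear either as slash-separated chemical names
#' ("Metformin Hydrochloride/Sitagliptin", the aggregated-dataset
#' convention) or as semicolon-separated constituent lists (the
#' patient-level CSV convention).
#'
#' @param name character vector of product names.
#' @return list of character vectors of constituents.
#' @export
split_constituents <- function(name) {
  out <- strsplit(name, "[/;+]")
  lapply(out, function(x) trimws(x[trimws(x) != ""]))
}

#' Resolve a (possibly combination) product to weighted classes
#'
#' Single-constituent products map to their class with weight 1. Products
#' combining metformin with one other agent follow the dataset convention:
#' in `patient_level` mode both constituent classes are counted (weight 1
#' each, so a first-ever combination start opens both classes); in
#' `aggregated` mode only the non-metformin class is counted. A mixture of
#' two non-metformin classes is counted as `"other"` in both modes.
#'
#' @param constituents character vector of constituent chemical names
#'   (length 1 or 2).
#' @param mode `"patient_level"` or `"aggregated"`.
#' @param class_map a `drug_class_map`.
#' @return list with `classes` (tibble of `class`, `weight`) and
#'   `unresolved` flag; if any constituent is unresolved, `classes` is
#'   empty and `unresolved` is `TRUE`.
#' @export
#' @examples
#' cm <- read_class_map()
#' resolve_combination(c("metformin", "sitagliptin"), "patient_level", cm)
#' resolve_combination(c("metformin", "rosiglitazone"), "aggregated", cm)
resolve_combination <- function(constituents, mode = c("patient_level", "aggregated"),
                                class_map) {
  mode <- match.arg(mode)
  if (length(constituents) < 1) stop("at least one constituent is required")
  if (length(constituents) > 2) {
    stop("combination products with more than 2 constituents are not supported: ",
         paste(constituents, collapse = " / "))
  }
  cls <- classify_chemical(constituents, class_map)
  if (anyNA(cls)) {
    return(list(
      classes = tibble::tibble(class = character(), weight = integer()),
      unresolved = TRUE
    ))
  }
  classes <- if (length(cls) == 1 || cls[1] == cls[2]) {
    tibble::tibble(class = cls[1], weight = 1L)
  } else if ("metformin" %in% cls) {
    non_met <- cls[cls != "metformin"][1]
    if (mode == "patient_level") {
      tibble::tibble(class = c("metformin", non_met), weight = c(1L, 1L))
    } else {
      tibble::tibble(class = non_met, weight = 1L)
    }
  } else {
    tibble::tibble(class = "other", weight = 1L)
  }
  list(classes = classes, unresolved = FALSE)
}

# Vectorised classification of product names (combinations included).
# Returns one row per (input item, class): tibble(item, class, weight).
# Unresolved names are dropped with a warning naming the offenders.
classify_items <- function(drug_names, mode, class_map) {
  uniq <- unique(drug_names)
  parts <- split_constituents(uniq)
  resolved <- lapply(parts, resolve_combination, mode = mode, class_map = class_map)
  bad <- vapply(resolved, `[[`, logical(1), "unresolved")
  if (any(bad)) {
    warning("unresolved drug name(s) dropped: ",
            paste(unique(uniq[bad]), collapse = ", "), call. = FALSE)
  }
  per_name <- lapply(seq_along(uniq), function(i) {
    cl <- resolved[[i]]$classes
    if (nrow(cl) == 0) return(NULL)
    tibble::tibble(drug_name = uniq[i], class = cl$class, weight = cl$weight)
  })
  map_tbl <- dplyr::bind_rows(per_name)
  out <- tibble::tibble(item = seq_along(drug_names), drug_name = drug_names)
  dplyr::inner_join(out, map_tbl, by = "drug_name",
                    relationship = "many-to-many")[, c("item", "class", "weight")]
}
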