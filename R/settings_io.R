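#' Load a personalization settings file
#'
#' Parses an XML settings file into a list of [personalization_task()]
#' objects.  Schema (version 1):
#'
#' ```
#' <PersonalizationSettings version="1">
#'   <Task name="glenohumeral" rate="20" maxiter="30" marker_file="all.trc">
#'     <JointParameter joint="glenohumeral" frame="parent" component="tx"/>
#'     <BodyScale body="clavicle" axis="x"/>
#'     <ConstraintPoint constraint="1" side="b" axis="x"/>
#'     <MarkerPosition body="scapula" marker="GC" axis="x"/>
#'   </Task>
#' </PersonalizationSettings>
#' ```
#'
#' `rate`, `maxiter` and `marker_file` are optional; unknown elements or
#' attributes are rejected with the offending element path.
#'
#' @param path XML file path.
#' @return list of [personalization_task()] objects.
#' @export
load_personalization_settings <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "PersonalizationSettings")
    stop("settings parse error at /: root element must be ",
         "PersonalizationSettings")
  ver <- xml2::xml_attr(doc, "version")
  if (is.na(ver) || ver != "1")
    stop("settings parse error at /PersonalizationSettings: ",
         "unsupported or missing version (expected \"1\")")
  tasks <- list()
  for (tnode in xml2::xml_children(doc)) {
    if (xml2::xml_name(tnode) != "Task")
      stop("settings parse error at /PersonalizationSettings/",
           xml2::xml_name(tnode), ": unknown element")
    attrs <- xml2::xml_attrs(tnode)
    extra <- setdiff(names(attrs), c("name", "rate", "maxiter",
                                     "marker_file"))
    if (length(extra))
      stop("settings parse error at /PersonalizationSettings/Task: ",
           "unknown attribute '", extra[1], "'")
    selectors <- lapply(xml2::xml_children(tnode), function(snode) {
      sa <- as.list(xml2::xml_attrs(snode))
      here <- paste0("/PersonalizationSettings/Task[@name='",
                     attrs[["name"]] %||% "", "']/", xml2::xml_name(snode))
      parse_attrs <- function(allowed) {
        extra <- setdiff(names(sa), c(allowed, "bounds"))
        if (length(extra))
          stop("settings parse error at ", here, ": unknown attribute '",
               extra[1], "'")
        missing <- setdiff(allowed, names(sa))
        if (length(missing))
          stop("settings parse error at ", here, ": missing attribute '",
               missing[1], "'")
        if (!is.null(sa$bounds))
          sa$bounds <<- as.numeric(strsplit(sa$bounds, ",")[[1]])
        sa
      }
      switch(xml2::xml_name(snode),
        JointParameter = {
          a <- parse_attrs(c("joint", "frame", "component"))
          select_joint_parameter(a$joint, a$frame, a$component, a$bounds)
        },
        BodyScale = {
          a <- parse_attrs(c("body", "axis"))
          select_body_scale(a$body, a$axis, a$bounds %||% c(0.5, 2))
        },
        MarkerPosition = {
          a <- parse_attrs(c("body", "marker", "axis"))
          select_marker_position(a$body, a$marker, a$axis, a$bounds)
        },
        ConstraintPoint = {
          a <- parse_attrs(c("constraint", "side", "axis"))
          select_constraint_point(as.integer(a$constraint), a$side, a$axis,
                                  a$bounds)
        },
        stop("settings parse error at ", here, ": unknown element"))
    })
    tasks <- c(tasks, list(personalization_task(
      markers = if (!is.na(attrs["marker_file"]))
        unname(attrs["marker_file"]) else NULL,
      selectors = selectors,
      rate = if (!is.na(attrs["rate"])) as.numeric(attrs["rate"]) else NULL,
      name = if (!is.na(attrs["name"])) unname(attrs["name"]) else "task",
      maxiter = if (!is.na(attrs["maxiter"]))
        as.integer(attrs["maxiter"]) else 30L)))
  }
  if (length(tasks) == 0) stop("settings file defines no tasks")
  tasks
}

#' Save personalization tasks to an XML settings file
#' @param tasks list of [personalization_task()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_personalization_settings <- function(tasks, path) {
  doc <- xml2::xml_new_root("PersonalizationSettings", version = "1")
  for (task in tasks) {
    tnode <- xml2::xml_add_child(doc, "Task", name = task$name)
    if (!is.null(task$rate)) xml2::xml_set_attr(tnode, "rate", task$rate)
    xml2::xml_set_attr(tnode, "maxiter", task$maxiter)
    if (is.character(task$markers))
      xml2::xml_set_attr(tnode, "marker_file", task$markers)
    for (s in task$selectors) {
      node <- switch(s$kind,
        joint_parameter = xml2::xml_add_child(
          tnode, "JointParameter", joint = s$joint, frame = s$frame,
          component = s$component),
        body_scale = xml2::xml_add_child(tnode, "BodyScale", body = s$body,
                                         axis = s$axis),
        marker_position = xml2::xml_add_child(
          tnode, "MarkerPosition", body = s$body, marker = s$marker,
          axis = s$axis),
        constraint_point = xml2::xml_add_child(
          tnode, "ConstraintPoint", constraint = s$constraint,
          side = s$side, axis = s$axis))
      if (!is.null(s$bounds) && s$kind != "body_scale")
        xml2::xml_set_attr(node, "bounds", paste(s$bounds, collapse = ","))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
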