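# Plain-text session serialization: a session directory holds behavior.csv
# (time, vx, vy), spikes.csv (unit_id, spike_time), units.csv (per-unit
# metadata) and meta.json.

#' Write a session to a plain-text directory
#'
#' @param sess a [session()].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(sess, path) {
  stopifnot(inherits(sess, "session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  beh <- sess$behavior
  utils::write.csv(data.frame(time = behavior_times(beh), vx = beh$vx,
                              vy = beh$vy),
                   file.path(path, "behavior.csv"), row.names = FALSE)
  spikes <- do.call(rbind, lapply(seq_along(sess$units), function(i)
    if (length(sess$units[[i]]$spike_times))
      data.frame(unit_id = i, spike_time = sess$units[[i]]$spike_times)))
  if (is.null(spikes))
    spikes <- data.frame(unit_id = integer(), spike_time = numeric())
  utils::write.csv(spikes, file.path(path, "spikes.csv"), row.names = FALSE)
  utils::write.csv(data.frame(
    unit_id = seq_along(sess$units),
    area = vapply(sess$units, `[[`, "", "area"),
    unit_class = vapply(sess$units, `[[`, "", "unit_class"),
    firing_rate = vapply(sess$units, `[[`, 0, "firing_rate")),
    file.path(path, "units.csv"), row.names = FALSE)
  jsonlite::write_json(list(task = sess$task, duration = sess$duration,
                            seed = sess$seed, dt = beh$dt, t0 = beh$t0,
                            tracking_noise_sd = beh$tracking_noise_sd),
                       file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a session from a plain-text directory
#'
#' @param path directory written by [write_session()].
#' @return a [session()].
#' @export
read_session <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  beh_df <- utils::read.csv(file.path(path, "behavior.csv"))
  beh <- behavior_trace(beh_df$vx, beh_df$vy, dt = meta$dt, t0 = meta$t0,
                        tracking_noise_sd = meta$tracking_noise_sd)
  spikes <- utils::read.csv(file.path(path, "spikes.csv"))
  units_df <- utils::read.csv(file.path(path, "units.csv"))
  units <- lapply(seq_len(nrow(units_df)), function(i) {
    st <- spikes$spike_time[spikes$unit_id == units_df$unit_id[i]]
    sorted_unit(st, unit_class = units_df$unit_class[i],
                area = units_df$area[i], duration = meta$duration)
  })
  session(beh, units, task = meta$task,
          seed = if (is.null(meta$seed)) NA_integer_ else meta$seed)
}
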