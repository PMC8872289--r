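# shared fixtures, all built in code

# a TrackSet from a list of per-track matrices/data.frames with
# columns frame, x, y
makeTrackSet <- function(trackList, frameInterval = 0.024,
                         condition = "test") {
  tr <- do.call(rbind, lapply(seq_along(trackList), function(i) {
    d <- as.data.frame(trackList[[i]])
    names(d) <- c("frame", "x", "y")
    cbind(track_id = i, d)
  }))
  trackSet(tr, frameInterval, condition)
}

# a straight track at constant velocity v (um/s)
driftTrack <- function(nFrames, v = 1, dt = 0.024) {
  data.frame(frame = 0:(nFrames - 1), x = v * dt * (0:(nFrames - 1)),
             y = 0)
}

# a stationary track at (x0, y0)
stillTrack <- function(nFrames, x0 = 0, y0 = 0) {
  data.frame(frame = 0:(nFrames - 1), x = rep(x0, nFrames),
             y = rep(y0, nFrames))
}

refParams <- divivaReferenceParameters()
stateD <- defaultStateDiffusion()
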