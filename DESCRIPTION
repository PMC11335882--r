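Package: fireseason
Title: Fire Weather, Burned-Area and Fire-Season Analytics on Gridded Weather and Hotspot Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse a continental wildfire season from gridded daily
    weather, 500-hPa geopotential heights, snow-cover and soil-moisture grids,
    satellite hotspot detections and fire perimeter data. Implements the
    Canadian Fire Weather Index System on grids with fire-season startup,
    shutdown and Drought Code overwintering; percentile-based extreme
    fire-weather climatologies and daily forested-extent statistics; detection
    of persistent positive 500-hPa height anomalies as a blocking proxy;
    snowmelt-timing and flash-drought metrics; hotspot buffering with ecozone
    calibration into hybrid burned-area composites; ordinary kriging of
    hotspot detection dates to per-pixel day-of-burn grids and daily
    area-burned series; and fire-level summaries (size classes, ignition
    timing, durations, potential spread days, power-law size relations, PM2.5
    exceedance counting). Includes a synthetic-data generator with a
    ground-truth bundle so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
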