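Package: whalenav
Title: Agent-Based Simulation of Baleen Whale Migration Under Ocean Noise
Version: 0.1.0
Authors@R:
    person("whalenav", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Simulates collective navigation of migrating baleen whales as a
    velocity-jump random walk with von Mises heading selection, acoustic
    detection of conspecifics subject to masking by ambient noise, negative
    phonotaxis (noise avoidance), bathotaxis (land avoidance) and passive
    advection by ocean currents. Includes a synthetic ocean-soundscape
    generator (wind noise floor, mobile vessel sources, duty-cycled
    construction sources), idealized bathymetry/current/coastline fixtures,
    scenario presets, ensemble trajectory metrics (Buchin median trajectory,
    arrivals, distance to target, detected conspecifics) and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
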