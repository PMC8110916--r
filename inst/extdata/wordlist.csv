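"word"
"a"
"about"
"action"
"air"
"all"
"almost"
"already"
"also"
"am"
"an"
"and"
"another"
"any"
"apron"
"are"
"area"
"art"
"as"
"ask"
"asked"
"asking"
"asks"
"at"
"away"
"back"
"be"
"beautiful"
"because"
"behind"
"beside"
"big"
"biscuit"
"biscuits"
"body"
"book"
"both"
"boy"
"brother"
"business"
"busy"
"but"
"by"
"cabinet"
"can"
"car"
"carefully"
"careless"
"chair"
"change"
"child"
"children"
"city"
"clean"
"climb"
"climbing"
"climbs"
"closet"
"cloth"
"community"
"company"
"completely"
"cookie"
"cookies"
"could"
"counter"
"country"
"cup"
"cupboard"
"cups"
"curtain"
"curtains"
"dangerously"
"daughter"
"day"
"daydream"
"daydreaming"
"did"
"dirty"
"dish"
"dishcloth"
"dishes"
"distracted"
"do"
"does"
"doing"
"done"
"door"
"down"
"dream"
"dreaming"
"dress"
"dries"
"drip"
"dripping"
"drips"
"drop"
"dropped"
"dry"
"drying"
"each"
"education"
"empty"
"end"
"every"
"everything"
"eye"
"face"
"fact"
"fall"
"fallen"
"falling"
"falls"
"family"
"far"
"father"
"faucet"
"feet"
"fell"
"finish"
"finished"
"floor"
"foot"
"force"
"forget"
"forgot"
"friend"
"from"
"full"
"game"
"garden"
"get"
"gets"
"getting"
"girl"
"go"
"goes"
"going"
"gone"
"government"
"grab"
"grabbing"
"group"
"guy"
"had"
"hand"
"handing"
"hands"
"has"
"have"
"he"
"head"
"health"
"her"
"high"
"him"
"his"
"history"
"hold"
"holding"
"home"
"hour"
"house"
"i"
"idea"
"ignore"
"ignores"
"ignoring"
"in"
"indifferent"
"information"
"into"
"is"
"issue"
"it"
"its"
"jar"
"jars"
"job"
"just"
"kid"
"kids"
"kind"
"kitchen"
"lady"
"laugh"
"laughing"
"laughs"
"law"
"leg"
"legs"
"level"
"lid"
"life"
"line"
"little"
"look"
"looking"
"looks"
"lot"
"man"
"may"
"maybe"
"meanwhile"
"member"
"might"
"minute"
"mom"
"moment"
"money"
"month"
"morning"
"mother"
"mr"
"my"
"name"
"near"
"nice"
"night"
"no"
"notice"
"noticed"
"notices"
"noticing"
"now"
"number"
"oblivious"
"of"
"off"
"office"
"oh"
"on"
"one"
"onto"
"open"
"or"
"others"
"out"
"outside"
"over"
"overflow"
"overflowed"
"overflowing"
"overflows"
"parent"
"party"
"path"
"person"
"picture"
"place"
"plate"
"plates"
"point"
"power"
"precariously"
"president"
"probably"
"problem"
"program"
"question"
"quickly"
"quietly"
"reach"
"reached"
"reaches"
"reaching"
"really"
"reason"
"research"
"result"
"room"
"run"
"running"
"runs"
"scene"
"school"
"seat"
"see"
"seem"
"seems"
"sees"
"service"
"she"
"shelf"
"shelves"
"side"
"sink"
"sister"
"slip"
"slipped"
"slipping"
"small"
"so"
"soapy"
"some"
"son"
"spill"
"spilled"
"spilling"
"spills"
"stand"
"standing"
"stands"
"state"
"steal"
"stealing"
"steals"
"still"
"stood"
"stool"
"stools"
"story"
"student"
"stuff"
"summer"
"sunny"
"system"
"take"
"taken"
"takes"
"taking"
"tall"
"tap"
"teacher"
"team"
"that"
"the"
"their"
"them"
"then"
"there"
"these"
"they"
"thing"
"things"
"this"
"those"
"three"
"three-legged"
"through"
"time"
"tip"
"tipping"
"tips"
"to"
"too"
"took"
"top"
"totally"
"towel"
"towels"
"try"
"trying"
"two"
"unaware"
"unconcerned"
"under"
"up"
"very"
"want"
"wanted"
"wanting"
"wants"
"war"
"warm"
"was"
"wash"
"washed"
"washes"
"washing"
"water"
"way"
"we"
"week"
"well"
"were"
"wet"
"what"
"which"
"while"
"who"
"will"
"wind"
"window"
"windows"
"wipe"
"wipes"
"wiping"
"with"
"wobble"
"wobbling"
"woman"
"women"
"wooden"
"word"
"work"
"world"
"would"
"yard"
"year"
"you"
"young"
"your"
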