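"unit","category","synonyms","anchors"
"boy","subject","boy|brother|son|kid","boy|child"
"girl","subject","girl|sister|daughter","girl|child"
"woman","subject","woman|mother|mom|lady","woman|mother"
"kitchen","place","kitchen","kitchen"
"window","place","window","window"
"curtains","place","curtain","curtain"
"cupboard","place","cupboard|cabinet|closet","cupboard"
"exterior","place","garden|yard|path|outside","garden|outside"
"sink","object","sink|faucet|tap","sink"
"water","object","water","water"
"dishes","object","dish","dish"
"plate","object","plate","plate"
"dishcloth","object","dishcloth|cloth|towel","cloth|towel"
"cookie","object","cookie|biscuit","cookie"
"jar","object","jar","jar"
"stool","object","stool","stool"
"overflow","action","overflow|spill|drip","overflow|spill"
"falling","action","fall|tip|wobble|slip|drop","fall|tip"
"taking","action","take|steal|grab|reach|climb","take|steal"
"washing","action","wash|dry|wipe","wash|dry"
"asking","action","ask","ask"
"unconcerned","action","unconcerned|indifferent|oblivious|unaware|distracted|daydream|ignore","unconcerned|oblivious"
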