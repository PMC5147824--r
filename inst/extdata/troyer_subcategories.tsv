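token	subcategories
rabbit	north-america,pet,farm,fur,rabbit
hare	rabbit,north-america,fur
bunny	rabbit,pet
cat	pet,feline
dog	pet,canine
tiger	feline,africa
lion	feline,africa
leopard	feline,africa
cheetah	feline,africa
panther	feline,north-america
cougar	feline,north-america
bobcat	feline,north-america
lynx	feline,north-america,arctic
jaguar	feline
zebra	africa
crocodile	africa,water,reptile-amphibian
whale	water
wolf	canine,north-america,arctic
fox	canine,north-america,fur
red-fox	canine,north-america,fur
gray-fox	canine,north-america,fur
coyote	canine,north-america
dingo	canine,australia
hyena	africa
bear	north-america,arctic,fur
horse	farm,beast-of-burden,pet
cow	farm,bovine
bull	farm,bovine
ox	farm,beast-of-burden,bovine
buffalo	north-america,bovine
bison	north-america,bovine
sheep	farm
goat	farm
pig	farm
chicken	farm,bird
turkey	farm,bird,north-america
duck	bird,water,farm,north-america
goose	bird,water,farm
eagle	bird,north-america
hawk	bird,north-america
owl	bird,north-america
robin	bird,north-america
parrot	bird,pet
canary	bird,pet
cockatiel	bird,pet
ostrich	bird,africa
penguin	bird,water,arctic
flamingo	bird,africa,water
trout	fish,water,north-america
salmon	fish,water,north-america
bass	fish,water,north-america
shark	fish,water
tuna	fish,water
goldfish	fish,water,pet
dolphin	water
seal	water,arctic,fur
walrus	water,arctic
otter	weasel,water,fur,north-america
mink	weasel,fur,north-america
skunk	weasel,north-america
ferret	weasel,pet
badger	weasel,north-america
weasel	weasel,north-america,fur
snake	reptile-amphibian
lizard	reptile-amphibian
turtle	reptile-amphibian,water,pet
frog	reptile-amphibian,water
toad	reptile-amphibian,water
alligator	reptile-amphibian,water,north-america
mouse	rodent,pet
rat	rodent
squirrel	rodent,north-america
hamster	rodent,pet
gerbil	rodent,pet
beaver	rodent,north-america,water,fur
porcupine	rodent,north-america
chipmunk	rodent,north-america
monkey	primate,africa
gorilla	primate,africa
chimpanzee	primate,africa
baboon	primate,africa
orangutan	primate
lemur	primate,africa
elephant	africa,beast-of-burden
giraffe	africa
hippopotamus	africa,water
rhinoceros	africa
gazelle	africa
antelope	africa,deer
deer	deer,north-america
moose	deer,north-america,arctic
elk	deer,north-america
caribou	deer,arctic,north-america
reindeer	deer,arctic
kangaroo	australia
koala	australia
wombat	australia
platypus	australia,water
camel	beast-of-burden,africa
donkey	farm,beast-of-burden
mule	farm,beast-of-burden
llama	beast-of-burden,farm
hedgehog	insectivore
mole	insectivore
shrew	insectivore
anteater	insectivore
aardvark	insectivore,africa
ant	insect
bee	insect
butterfly	insect
beetle	insect
grasshopper	insect
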