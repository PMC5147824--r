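# animals category lexicon (accepted tokens, one per line)
rabbit
hare
bunny
cat
dog
tiger
lion
leopard
cheetah
panther
cougar
bobcat
lynx
jaguar
zebra
crocodile
whale
wolf
fox
red-fox
gray-fox
coyote
dingo
hyena
bear
horse
cow
bull
ox
buffalo
bison
sheep
goat
pig
chicken
turkey
duck
goose
eagle
hawk
owl
robin
parrot
canary
cockatiel
ostrich
penguin
flamingo
trout
salmon
bass
shark
tuna
goldfish
dolphin
seal
walrus
otter
mink
skunk
ferret
badger
weasel
snake
lizard
turtle
frog
toad
alligator
mouse
rat
squirrel
hamster
gerbil
beaver
porcupine
chipmunk
monkey
gorilla
chimpanzee
baboon
orangutan
lemur
elephant
giraffe
hippopotamus
rhinoceros
gazelle
antelope
deer
moose
elk
caribou
reindeer
kangaroo
koala
wombat
platypus
camel
donkey
mule
llama
hedgehog
mole
shrew
anteater
aardvark
ant
bee
butterfly
beetle
grasshopper
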