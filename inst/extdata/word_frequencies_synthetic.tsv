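token	count
rabbit	56
hare	1683
bunny	1993
cat	11511
dog	34644
tiger	44
lion	1567
leopard	79
cheetah	1106
panther	950
cougar	1685
bobcat	365
lynx	304
jaguar	137
zebra	635
crocodile	923
whale	25
wolf	38
fox	161
red-fox	44
gray-fox	74
coyote	78
dingo	936
hyena	17
bear	45977
horse	8726
cow	8629
bull	33
ox	152
buffalo	149
bison	93
sheep	16211
goat	50
pig	13360
chicken	30963
turkey	761
duck	14278
goose	17
eagle	32
hawk	1610
owl	154
robin	120
parrot	152
canary	27
cockatiel	143
ostrich	51
penguin	144
flamingo	22
trout	1955
salmon	1015
bass	691
shark	42
tuna	1302
goldfish	132
dolphin	361
seal	313
walrus	87
otter	111
mink	225
skunk	387
ferret	36
badger	1563
weasel	125
snake	1797
lizard	969
turtle	86
frog	1271
toad	37
alligator	1172
mouse	22761
rat	10832
squirrel	37
hamster	610
gerbil	986
beaver	43
porcupine	38
chipmunk	38
monkey	719
gorilla	72
chimpanzee	29
baboon	835
orangutan	412
lemur	41
elephant	369
giraffe	24
hippopotamus	30
rhinoceros	42
gazelle	425
antelope	779
deer	348
moose	38
elk	1298
caribou	1655
reindeer	1103
kangaroo	302
koala	84
wombat	21
platypus	130
camel	219
donkey	374
mule	26
llama	74
hedgehog	334
mole	899
shrew	1122
anteater	1573
aardvark	34
ant	36
bee	159
butterfly	105
beetle	1737
grasshopper	53
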