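subject_id,condition,category,duration_s,token,onset_s,age,education,computer_use
demo01,semantic,animals,90,dog,1.8,34,16,6
demo01,semantic,animals,90,cat,3.1,34,16,6
demo01,semantic,animals,90,hamster,5.9,34,16,6
demo01,semantic,animals,90,goldfish,9.4,34,16,6
demo01,semantic,animals,90,lion,14.2,34,16,6
demo01,semantic,animals,90,tiger,15.8,34,16,6
demo01,semantic,animals,90,leopard,19.0,34,16,6
demo01,semantic,animals,90,zebra,24.7,34,16,6
demo01,semantic,animals,90,giraffe,26.3,34,16,6
demo01,semantic,animals,90,elephant,29.5,34,16,6
demo01,semantic,animals,90,trout,38.2,34,16,6
demo01,semantic,animals,90,salmon,40.1,34,16,6
demo01,semantic,animals,90,shark,44.9,34,16,6
demo01,semantic,animals,90,whale,48.8,34,16,6
demo01,semantic,animals,90,dolphin,52.6,34,16,6
demo01,semantic,animals,90,eagle,61.3,34,16,6
demo01,semantic,animals,90,hawk,64.0,34,16,6
demo01,semantic,animals,90,owl,67.7,34,16,6
demo01,semantic,animals,90,dog,75.2,34,16,6
demo01,semantic,animals,90,moose,82.4,34,16,6
demo01,semantic,animals,90,elk,86.9,34,16,6
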